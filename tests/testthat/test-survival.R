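surv_tab <- function(time, event, covariate = seq_along(time)) {
  data.frame(sample = paste0("s", seq_along(time)), time = time,
             event = event, covariate = covariate, stringsAsFactors = FALSE)
}

test_that("median split assigns ties to the low group", {
  rec <- surv_tab(1:4, rep(1, 4), covariate = c(1, 2, 3, 4))
  expect_identical(as.character(median_split(rec)),
                   c("low", "low", "high", "high"))
  tied <- surv_tab(1:5, rep(1, 5), covariate = c(1, 2, 2, 3, 4))
  expect_identical(as.character(median_split(tied)),
                   c("low", "low", "low", "high", "high"))
  expect_error(median_split(surv_tab(1:4, rep(1, 4), covariate = rep(7, 4))),
               "degenerate")
  expect_error(median_split(surv_tab(1:3, rep(1, 3))),
               class = "fflmotif_invalid_parameter")
})

test_that("median split group sizes differ by at most the number of ties", {
  for (s in 1:25) {
    cov <- withr::with_seed(100 + s, sample(1:10, 20, replace = TRUE))
    rec <- surv_tab(1:20, rep(1, 20), covariate = cov)
    grp <- median_split(rec)
    # ties at the median all drop to "low"; without ties the split is
    # balanced to within one sample, and each tie can displace at most two
    n_ties <- sum(cov == median(cov))
    expect_lte(abs(sum(grp == "high") - sum(grp == "low")),
               max(1L, 2L * n_ties))
  }
})

test_that("KM estimator matches hand-traced product-limit tables", {
  # 4 deaths, no censoring: S drops by 1/4 at each time
  rec <- surv_tab(1:4, rep(1, 4))
  km <- km_estimate(rec)
  expect_equal(km$times, 1:4)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$at_risk, 4:1)

  # censoring between events: {(1, death), (2, censor), (3, death)}
  # S(1) = 2/3; at t = 3 one subject at risk, so S(3) = 2/3 * 0 = 0
  rec2 <- surv_tab(c(1, 2, 3), c(1, 0, 1))
  km2 <- km_estimate(rec2)
  expect_equal(km2$times, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))

  expect_warning(flat <- km_estimate(surv_tab(1:5, rep(0, 5))), "no events")
  expect_length(flat$times, 0L)
})

test_that("KM equals the empirical survival function without censoring", {
  for (s in 1:30) {
    rec <- random_survival(5 + (s * 13) %% 196, censor_frac = 0,
                           seed = 1200 + s)
    km <- km_estimate(rec)
    ecdf_surv <- vapply(km$times, function(t) mean(rec$time > t), numeric(1))
    expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
    ref <- oracle_km(rec$time, rec$event)
    expect_equal(km$survival, ref$survival, tolerance = 1e-12)
  }
})

test_that("KM survival values are nonincreasing under censoring too", {
  for (s in 1:20) {
    rec <- random_survival(60, censor_frac = 0.4, seed = 1500 + s)
    km <- km_estimate(rec)
    expect_true(all(km$survival >= -1e-12 & km$survival <= 1 + 1e-12))
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(diff(km$at_risk) <= 0))
  }
})

test_that("log-rank matches the manual O/E/V computation on small datasets", {
  for (s in 1:40) {
    rec <- random_survival(6L + s %% 3L, censor_frac = 0.25, seed = 1700 + s)
    grp <- ifelse(rec$covariate > median(rec$covariate), "high", "low")
    if (length(unique(grp)) < 2) next
    got <- log_rank(rec, grp, invert_hr = FALSE)
    ref <- oracle_logrank(rec$time, rec$event, grp == "high")
    if (!is.finite(ref$chi2)) next
    expect_equal(got$chi2, ref$chi2, tolerance = 1e-8)
    expect_equal(got$p_value, ref$p, tolerance = 1e-8)
    expect_equal(got$hr, ref$hr, tolerance = 1e-8)
  }
})

test_that("identical groups give chi2 = 0, p = 1, hr = 1", {
  one_arm <- random_survival(15, censor_frac = 0.2, seed = 2100)
  rec <- rbind(one_arm, one_arm)
  rec$sample <- paste0("s", seq_len(nrow(rec)))
  grp <- rep(c("high", "low"), each = 15)
  res <- log_rank(rec, grp)
  expect_equal(res$chi2, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_equal(res$hr, 1, tolerance = 1e-9)
  expect_false(res$inverted)
})

test_that("HR inversion reports the adverse orientation and is an involution", {
  rec <- generate_survival(200, 0.05, 1.0,
                           covariate = withr::with_seed(5, rnorm(200)),
                           censor_rate = 0.02, seed = 6)
  grp <- median_split(rec)
  raw <- log_rank(rec, grp, invert_hr = FALSE)
  inv <- log_rank(rec, grp, invert_hr = TRUE)
  if (raw$hr < 1) {
    expect_true(inv$inverted)
    expect_equal(inv$hr, 1 / raw$hr)
  } else {
    expect_false(inv$inverted)
    expect_equal(inv$hr, raw$hr)
  }
  expect_gte(inv$hr, 1)
  # chi2 is invariant under swapping the group labels
  swapped <- ifelse(grp == "high", "low", "high")
  expect_equal(log_rank(rec, swapped, invert_hr = FALSE)$chi2, raw$chi2,
               tolerance = 1e-9)
})

test_that("null log-rank p-values are approximately uniform", {
  ps <- vapply(1:400, function(s) {
    rec <- generate_survival(60, 0.05, 0,
                             covariate = withr::with_seed(9000 + s, rnorm(60)),
                             censor_rate = 0.02, seed = 40000 + s)
    log_rank(rec, median_split(rec))$p_value
  }, numeric(1))
  expect_lt(unname(ks.test(ps, "punif")$statistic), 0.07)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("covariate scan ranks a planted prognostic CpG first", {
  hits <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    n <- 120L
    meth <- generate_methylation(20, n, alpha = 2, beta = 5, seed = 700 + s)
    planted <- meth["cg00000001", ]
    rec <- generate_survival(n, 0.05, 1.2, covariate = planted,
                             censor_rate = 0.02, seed = 800 + s)
    scan <- covariate_scan(meth, rec)
    hits <- hits + (scan$feature[1] == "cg00000001")
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("covariate scan is consistent with a direct log-rank call", {
  rec <- random_survival(50, censor_frac = 0.2, seed = 2500)
  m <- matrix(withr::with_seed(3, rnorm(50)), nrow = 1,
              dimnames = list("F1", rec$sample))
  scan <- covariate_scan(m, rec)
  rec$covariate <- m["F1", rec$sample]
  direct <- log_rank(rec, median_split(rec))
  expect_equal(scan$p_value, direct$p_value)
  expect_equal(scan$chi2, direct$chi2)
  expect_equal(scan$hr, direct$hr)
})

test_that("covariate scan skips degenerate features with a message", {
  rec <- random_survival(20, censor_frac = 0.2, seed = 2600)
  m <- rbind(F1 = rep(0.5, 20),
             F2 = withr::with_seed(4, rnorm(20)))
  colnames(m) <- rec$sample
  expect_message(scan <- covariate_scan(m, rec), "degenerate")
  expect_identical(scan$feature, "F2")
})

test_that("methylation heatmap ordering follows the requested key", {
  rec <- random_survival(40, censor_frac = 0.2, seed = 2700)
  m <- generate_methylation(10, 40, seed = 11, sample_ids = rec$sample)
  by_mean <- methylation_heatmap_table(m, "by_mean")
  expect_true(!is.unsorted(-rowMeans(by_mean$matrix)))
  expect_identical(dim(by_mean$matrix), dim(m))
  expect_identical(sort(rownames(by_mean$matrix)), sort(rownames(m)))

  by_p <- methylation_heatmap_table(m, "by_p", records = rec)
  scan <- covariate_scan(m, rec)
  expect_identical(rownames(by_p$matrix), scan$feature)
  expect_error(methylation_heatmap_table(m, "by_p"),
               class = "fflmotif_invalid_parameter")
  expect_error(methylation_heatmap_table(m, "nope"))
})
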