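# Independent oracles used to cross-check the implementation. Each is written
# from first principles (brute force or textbook formula) and never calls the
# package function it validates.

# brute-force triangle count/list over explicit edge tables: loop over every
# (tf, gene, mirna) combination and test membership of the three edges
oracle_ffls <- function(tf_gene, mir_gene, mir_tf) {
  tfs <- unique(c(tf_gene$tf, mir_tf$target))
  genes <- unique(c(tf_gene$gene, mir_gene$target))
  mirnas <- unique(c(mir_gene$mirna, mir_tf$mirna))
  tg_keys <- paste(tf_gene$tf, tf_gene$gene, sep = "\r")
  mt_keys <- paste(mir_tf$mirna, mir_tf$target, sep = "\r")
  mg_keys <- paste(mir_gene$mirna, mir_gene$target, sep = "\r")
  out <- list()
  for (t in tfs) for (g in genes) for (m in mirnas) {
    if (paste(t, g, sep = "\r") %in% tg_keys &&
        paste(m, t, sep = "\r") %in% mt_keys &&
        paste(m, g, sep = "\r") %in% mg_keys) {
      out[[length(out) + 1L]] <- data.frame(tf = t, gene = g, mirna = m,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(tf = character(0), gene = character(0),
                      mirna = character(0), stringsAsFactors = FALSE))
  }
  tri <- do.call(rbind, out)
  tri[order(tri$tf, tri$gene, tri$mirna), , drop = FALSE]
}

# explicit combinatorial hypergeometric upper tail:
# P(X >= k) with K set members, N universe, n drawn
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# textbook Welch t-test evaluated from the closed-form formulas
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# manual product-limit estimator at each distinct event time
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (i in seq_along(et)) {
    n_risk <- sum(time >= et[i])
    d <- sum(time == et[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(times = et, survival = surv)
}

# manual two-group log-rank: accumulate O, E, V over distinct event times
oracle_logrank <- function(time, event, group_high) {
  et <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  O0 <- E0 <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group_high)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group_high)
    O1 <- O1 + d1
    O0 <- O0 + (d - d1)
    E1 <- E1 + d * n1 / n
    E0 <- E0 + d * (n - n1) / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
       hr = (O1 / E1) / (O0 / E0))
}

# random edge tables over small namespaces, for property tests
random_edge_tables <- function(n_tf, n_gene, n_mirna, p, seed) {
  withr::with_seed(seed, {
    grid_tg <- expand.grid(tf = paste0("T", seq_len(n_tf)),
                           gene = paste0("g", seq_len(n_gene)),
                           stringsAsFactors = FALSE)
    grid_mt <- expand.grid(mirna = paste0("m", seq_len(n_mirna)),
                           target = paste0("T", seq_len(n_tf)),
                           stringsAsFactors = FALSE)
    grid_mg <- expand.grid(mirna = paste0("m", seq_len(n_mirna)),
                           target = paste0("g", seq_len(n_gene)),
                           stringsAsFactors = FALSE)
    list(tf_gene = grid_tg[runif(nrow(grid_tg)) < p, , drop = FALSE],
         mir_tf = grid_mt[runif(nrow(grid_mt)) < p, , drop = FALSE],
         mir_gene = grid_mg[runif(nrow(grid_mg)) < p, , drop = FALSE])
  })
}

# small uncensored/censored random survival tables
random_survival <- function(n, censor_frac, seed) {
  withr::with_seed(seed, {
    data.frame(sample = paste0("s", seq_len(n)),
               time = round(rexp(n, 0.1), 3) + 0.001,
               event = as.integer(runif(n) > censor_frac),
               covariate = rnorm(n),
               stringsAsFactors = FALSE)
  })
}
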