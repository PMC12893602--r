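#' Median split of a cohort by covariate
#'
#' Dichotomises samples at the median of the covariate computed over the
#' entire cohort: strictly above the median is `"high"`, at or below is
#' `"low"` (median ties go to the low group).
#'
#' @param records survival data frame `sample`, `time`, `event`, `covariate`
#'   with at least 4 rows.
#' @return A factor of labels with levels `low`, `high`, one per record.
#' @export
median_split <- function(records) {
  if (nrow(records) < 4L) abort_invalid("median split needs >= 4 records")
  cov <- records$covariate
  if (length(unique(cov)) == 1L) {
    stop("degenerate split: all covariate values are identical")
  }
  med <- stats::median(cov)
  factor(ifelse(cov > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' Estimates the survival curve over the distinct event times, with samples
#' censored at an event time counted as still at risk at that time (the
#' standard convention). Backed by [survival::survfit()].
#'
#' @param records survival data frame `sample`, `time`, `event`, `covariate`.
#' @return An object of class `km_curve`: list with `times` (increasing
#'   distinct event times), `survival` (estimated S(t) just after each event
#'   time), `at_risk` (numbers at risk just before each event time), and
#'   `n_events`. With zero events the curve is flat at 1 (all fields empty)
#'   and a warning is raised.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) abort_invalid("`records` must be non-empty")
  if (sum(records$event) == 0) {
    warning("no events: survival curve is flat at 1")
    return(structure(list(times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n_events = integer(0)),
                     class = "km_curve"))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n_events = fit$n.event[keep]),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d event times, final S(t) = %.3f\n",
              length(x$times),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' Two-group log-rank test with O/E hazard-ratio approximation
#'
#' Standard 1-df log-rank chi-square comparing the `high` and `low` groups,
#' backed by [survival::survdiff()]. The hazard ratio is the
#' observed/expected approximation `(O_high/E_high) / (O_low/E_low)` — the
#' log-rank HR, not a Cox-model estimate. With `invert_hr = TRUE` (the
#' default, mirroring the common "invert HR values below 1" reporting
#' convention) a ratio below 1 is reported as its reciprocal with
#' `inverted = TRUE`, so the reported HR always highlights the
#' adversely-surviving orientation.
#'
#' @param records survival data frame `sample`, `time`, `event`, `covariate`.
#' @param groups factor/character per record with values `"high"`/`"low"`
#'   (e.g. from [median_split()]); both groups must be non-empty.
#' @param invert_hr report `max(hr, 1/hr)` with an `inverted` flag?
#' @return A list of class `log_rank_result`: `chi2`, `p_value`, `hr`,
#'   `n_high`, `n_low`, `inverted`.
#' @export
log_rank <- function(records, groups, invert_hr = TRUE) {
  groups <- as.character(groups)
  if (length(groups) != nrow(records)) {
    abort_invalid("`groups` must have one label per record")
  }
  if (!all(groups %in% c("high", "low"))) {
    abort_invalid("group labels must be 'high' or 'low'")
  }
  if (length(unique(groups)) != 2L) {
    abort_invalid("both groups must contain at least one subject")
  }
  g <- factor(groups, levels = c("low", "high"))
  dat <- data.frame(time = records$time, event = records$event, g = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  if (any(sd$exp == 0)) stop("a group accrues zero expected events")
  chi2 <- unname(sd$chisq)
  hr <- (sd$obs[2L] / sd$exp[2L]) / (sd$obs[1L] / sd$exp[1L])
  hr <- unname(hr)
  inverted <- FALSE
  if (invert_hr && is.finite(hr) && hr > 0 && hr < 1) {
    hr <- 1 / hr
    inverted <- TRUE
  }
  structure(list(chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 hr = hr,
                 n_high = sum(g == "high"), n_low = sum(g == "low"),
                 inverted = inverted),
            class = "log_rank_result")
}

#' @export
print.log_rank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.3f, p = %.4g, HR = %.3f%s (%d high / %d low)\n",
              x$chi2, x$p_value, x$hr,
              if (x$inverted) " (inverted)" else "", x$n_high, x$n_low))
  invisible(x)
}

#' Per-feature survival scan over a covariate matrix
#'
#' For every row of the matrix (a gene's expression or a CpG's beta values
#' across samples), performs a cohort-wide median split and a log-rank test,
#' and returns one result row per feature sorted by ascending p-value.
#' Degenerate features (constant across samples, or splitting into a single
#' group) are skipped with a message.
#'
#' @param matrix numeric matrix, features x samples; column names must cover
#'   the `sample` ids in `records`.
#' @param records survival data frame `sample`, `time`, `event`.
#' @param invert_hr see [log_rank()].
#' @return A data frame `feature`, `chi2`, `p_value`, `hr`, `inverted`,
#'   `n_high`, `n_low`, sorted by `p_value`.
#' @export
covariate_scan <- function(matrix, records, invert_hr = TRUE) {
  if (!all(records$sample %in% colnames(matrix))) {
    abort_invalid("matrix columns do not cover the survival sample ids")
  }
  m <- matrix[, records$sample, drop = FALSE]
  rows <- lapply(rownames(m), function(f) {
    rec <- records
    rec$covariate <- m[f, ]
    res <- tryCatch({
      grp <- median_split(rec)
      if (length(unique(grp)) != 2L) stop("single-group split")
      log_rank(rec, grp, invert_hr = invert_hr)
    }, error = function(e) NULL)
    if (is.null(res)) {
      message("covariate_scan: skipping degenerate feature ", f)
      return(NULL)
    }
    data.frame(feature = f, chi2 = res$chi2, p_value = res$p_value,
               hr = res$hr, inverted = res$inverted,
               n_high = res$n_high, n_low = res$n_low,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(0), chi2 = numeric(0),
                      p_value = numeric(0), hr = numeric(0),
                      inverted = logical(0), n_high = integer(0),
                      n_low = integer(0))
  }
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heatmap-ready ordering of a methylation matrix
#'
#' Reorders rows for display without touching the values: `by_mean` sorts by
#' decreasing row mean (most methylated CpG first); `by_p` sorts by the
#' per-CpG log-rank p-value from [covariate_scan()] and therefore requires
#' `records`.
#'
#' @param matrix CpG x samples beta-value matrix.
#' @param order `"by_mean"` or `"by_p"`.
#' @param records survival table, required for `order = "by_p"`.
#' @return A list with `matrix` (rows reordered) and `annotations`
#'   (data frame `feature`, `key` holding the ordering statistic).
#' @export
methylation_heatmap_table <- function(matrix, order = c("by_mean", "by_p"),
                                      records = NULL) {
  order <- match.arg(order)
  if (order == "by_mean") {
    key <- rowMeans(matrix)
    idx <- base::order(-key)
    ann <- data.frame(feature = rownames(matrix)[idx], key = key[idx],
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(records)) abort_invalid("`records` required for order = 'by_p'")
    scan <- covariate_scan(matrix, records)
    idx <- match(scan$feature, rownames(matrix))
    ann <- data.frame(feature = scan$feature, key = scan$p_value,
                      stringsAsFactors = FALSE)
  }
  list(matrix = matrix[idx, , drop = FALSE], annotations = ann)
}
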