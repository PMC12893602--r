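#' Collapse duplicate feature identifiers
#'
#' Microarray matrices often carry several probes per feature id; downstream
#' screening expects one row per id. `max_mean` keeps, per id, the row with
#' the highest mean expression (the conventional "most responsive probe"
#' rule); `mean` averages all rows sharing an id.
#'
#' @param x an [expression_matrix()] (duplicate row names allowed).
#' @param policy `"max_mean"` or `"mean"`.
#' @return An `expr_matrix` with unique row names, in first-appearance order.
#' @export
collapse_duplicates <- function(x, policy = c("max_mean", "mean")) {
  stopifnot(inherits(x, "expr_matrix"))
  policy <- match.arg(policy)
  v <- x$values
  ids <- rownames(v)
  if (!anyDuplicated(ids)) return(x)
  keep_order <- unique(ids)
  if (policy == "max_mean") {
    means <- rowMeans(v)
    pick <- vapply(keep_order, function(id) {
      rows <- which(ids == id)
      rows[which.max(means[rows])]
    }, integer(1))
    out <- v[pick, , drop = FALSE]
  } else {
    out <- t(vapply(keep_order, function(id) {
      colMeans(v[ids == id, , drop = FALSE])
    }, numeric(ncol(v))))
  }
  rownames(out) <- keep_order
  expression_matrix(out, as.character(x$group))
}

#' Quantile-normalise an expression matrix
#'
#' Makes every column share the same empirical distribution (the row-wise mean
#' of the column-sorted values); ties receive the mean over their tied
#' positions. Backed by [limma::normalizeQuantiles()].
#'
#' @param x an [expression_matrix()] without missing values.
#' @return The normalised `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (anyNA(x$values)) stop("missing values are not supported")
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, as.character(x$group))
}

#' Two-sample t-test for one feature
#'
#' Returns the log2 fold change (mean of case minus mean of control), the
#' t statistic and the two-sided p-value, using Welch's unequal-variance test
#' by default or the pooled-variance test. When both groups are constant and
#' equal the result is defined as t = 0, p = 1 (no evidence of change); when
#' both are constant but unequal, t is signed infinite and p = 0.
#'
#' @param case_values,control_values numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A named list `log2_fc`, `t_stat`, `p_value`.
#' @export
test_feature <- function(case_values, control_values,
                         variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(case_values) < 2L || length(control_values) < 2L) {
    abort_invalid("each group needs at least 2 observations")
  }
  fc <- mean(case_values) - mean(control_values)
  if (stats::sd(case_values) == 0 && stats::sd(control_values) == 0) {
    if (fc == 0) return(list(log2_fc = 0, t_stat = 0, p_value = 1))
    return(list(log2_fc = fc, t_stat = sign(fc) * Inf, p_value = 0))
  }
  tt <- stats::t.test(case_values, control_values,
                      var.equal = (variant == "pooled"))
  list(log2_fc = fc, t_stat = unname(tt$statistic), p_value = tt$p.value)
}

#' Fold-change decision rules
#'
#' `fc_band()` declares a feature fold-change-eligible when
#' `lo <= |log2FC| <= hi`; this is the screen's default, which deliberately
#' targets moderate shifts and excludes extreme ones. `fc_min()` is the
#' conventional single-threshold rule `|log2FC| >= lo`.
#'
#' @param lo,hi band limits in absolute log2-fold-change units.
#' @return An object of class `fc_rule`.
#' @export
fc_band <- function(lo = 0.5, hi = 1.0) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || lo > hi) {
    abort_invalid("`fc_band` needs 0 <= lo <= hi")
  }
  structure(list(rule = "band", lo = lo, hi = hi), class = "fc_rule")
}

#' @rdname fc_band
#' @export
fc_min <- function(lo = 0.5) {
  if (!is.numeric(lo) || lo < 0) abort_invalid("`fc_min` needs lo >= 0")
  structure(list(rule = "min", lo = lo), class = "fc_rule")
}

fc_pass <- function(rule, log2_fc) {
  a <- abs(log2_fc)
  switch(rule$rule,
         band = a >= rule$lo & a <= rule$hi,
         min = a >= rule$lo)
}

#' Screen all features for differential expression
#'
#' Runs [test_feature()] on every row of the matrix and flags features as
#' differentially expressed when the (optionally BH-adjusted) p-value falls
#' below `p_thresh` and the absolute log2 fold change satisfies `fc_rule`.
#' The fold change is oriented case minus control (tumour minus control under
#' the conventional design).
#'
#' @param x an [expression_matrix()], one row per unique feature.
#' @param p_thresh significance threshold (strict `<`), default 0.05.
#' @param fc_rule an [fc_band()] (default `fc_band(0.5, 1.0)`) or [fc_min()].
#' @param adjust `"none"` (raw p, default) or `"bh"`
#'   (Benjamini-Hochberg; the adjusted p is then used for the DE call).
#' @param variant t-test variant, see [test_feature()].
#' @return A data frame with one row per feature: `feature_id`, `log2_fc`,
#'   `t_stat`, `p_value`, `adj_p`, `is_de`, `direction`
#'   (`"up"` / `"down"` / `"none"`).
#' @export
run_de <- function(x, p_thresh = 0.05, fc_rule = fc_band(0.5, 1.0),
                   adjust = c("none", "bh"), variant = c("welch", "pooled")) {
  stopifnot(inherits(x, "expr_matrix"), inherits(fc_rule, "fc_rule"))
  adjust <- match.arg(adjust)
  variant <- match.arg(variant)
  p_thresh <- check_prob(p_thresh, "p_thresh")
  if (anyDuplicated(rownames(x$values))) {
    abort_invalid("duplicate feature ids; apply collapse_duplicates() first")
  }
  case <- x$values[, x$group == "case", drop = FALSE]
  ctrl <- x$values[, x$group == "control", drop = FALSE]
  res <- lapply(seq_len(nrow(x$values)), function(i) {
    test_feature(case[i, ], ctrl[i, ], variant = variant)
  })
  log2_fc <- vapply(res, `[[`, numeric(1), "log2_fc")
  t_stat <- vapply(res, `[[`, numeric(1), "t_stat")
  p_value <- vapply(res, `[[`, numeric(1), "p_value")
  adj_p <- if (adjust == "bh") stats::p.adjust(p_value, "BH") else p_value
  p_used <- if (adjust == "bh") adj_p else p_value
  is_de <- p_used < p_thresh & fc_pass(fc_rule, log2_fc)
  data.frame(
    feature_id = rownames(x$values),
    log2_fc = log2_fc,
    t_stat = t_stat,
    p_value = p_value,
    adj_p = adj_p,
    is_de = is_de,
    direction = ifelse(!is_de, "none", ifelse(log2_fc > 0, "up", "down")),
    stringsAsFactors = FALSE
  )
}

#' Up/down/total bookkeeping of a differential screen
#'
#' @param results a [run_de()] table.
#' @return A list with counts `up`, `down`, `de_total` (up + down), `none`,
#'   and `total` (all features tested).
#' @export
de_summary <- function(results) {
  up <- sum(results$direction == "up")
  down <- sum(results$direction == "down")
  list(up = up, down = down, de_total = up + down,
       none = sum(results$direction == "none"), total = nrow(results))
}

#' Volcano-plot-ready table
#'
#' @param results a non-empty [run_de()] table.
#' @return A data frame `feature_id`, `log2_fc`, `neg_log10_p`
#'   (`-log10(p)`, with p = 0 clamped to the smallest positive double and a
#'   message emitted), `significant` (mirrors `is_de`).
#' @export
volcano_table <- function(results) {
  if (!nrow(results)) abort_invalid("`results` must be non-empty")
  p <- results$p_value
  if (any(p == 0)) {
    message(sum(p == 0), " zero p-value(s) clamped for -log10 transform")
    p[p == 0] <- .Machine$double.xmin
  }
  data.frame(
    feature_id = results$feature_id,
    log2_fc = results$log2_fc,
    neg_log10_p = -log10(p),
    significant = results$is_de,
    stringsAsFactors = FALSE
  )
}

#' Top up- and down-regulated features
#'
#' Selects the `k` most up-regulated (largest log2FC among DE-up) and `k` most
#' down-regulated (smallest log2FC among DE-down) features. Ties break by
#' smaller p-value, then lexicographic feature id. If fewer than `k` features
#' are available in a direction, all of them are returned with a warning.
#'
#' @param results a [run_de()] table.
#' @param k features per direction, default 10.
#' @return The selected rows of `results`, up block first.
#' @export
top_k_table <- function(results, k = 10) {
  k <- check_count(k, "k")
  pick <- function(direction) {
    rows <- results[results$direction == direction, , drop = FALSE]
    sgn <- if (direction == "up") -1 else 1
    rows <- rows[order(sgn * rows$log2_fc, rows$p_value, rows$feature_id), ,
                 drop = FALSE]
    if (nrow(rows) < k) {
      warning(sprintf("only %d %s-regulated DE features available (k = %d)",
                      nrow(rows), direction, k))
    }
    utils::head(rows, k)
  }
  out <- rbind(pick("up"), pick("down"))
  rownames(out) <- NULL
  out
}
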