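#' Read and write GMT gene-set files
#'
#' Standard GMT dialect: one set per line, tab-separated as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a set are dropped on read; a line with fewer than three fields is a parse
#' error reported with its line number.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `read_gmt()` returns a named list of unique member vectors;
#'   `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT parse error: line %d has fewer than 3 fields", short[1L]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(name, desc, members) {
    paste(c(name, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' One-sided hypergeometric test per gene set: with a universe of size N, a
#' set of size K (after intersecting the set with the universe), and a DE
#' list of size n, the p-value is the upper tail P(X >= overlap) of the
#' hypergeometric distribution. P-values are BH-adjusted across all tested
#' sets; the reported table is sorted by p (ties by set name) and truncated
#' to the `top_k` sets with p < `p_thresh`.
#'
#' @param de_genes character vector, the differential gene list; must be a
#'   subset of `universe`.
#' @param universe character vector of all tested genes.
#' @param sets named list of character vectors (see [read_gmt()]).
#' @param p_thresh significance threshold on the raw p-value, default 0.05;
#'   `p_thresh = 1` disables the significance filter (all sets reported).
#' @param top_k rows to report, default 10; use `Inf` for the full table.
#' @return A data frame `set_name`, `overlap`, `set_size` (within-universe),
#'   `list_size`, `universe_size`, `p_value`, `adj_p`, `overlap_genes`
#'   (comma-joined).
#' @export
ora <- function(de_genes, universe, sets, p_thresh = 0.05, top_k = 10) {
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  p_thresh <- check_prob(p_thresh, "p_thresh")
  outside <- setdiff(de_genes, universe)
  if (length(outside)) {
    stop("de_genes not in universe: ", paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    hits <- intersect(members, de_genes)
    ov <- length(hits)
    # P(X >= ov), hypergeometric upper tail; K = 0 or ov = 0 give p = 1
    p <- stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = K, list_size = n,
               universe_size = N, p_value = p,
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(set_name = character(0), overlap = integer(0),
                      set_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      adj_p = numeric(0), overlap_genes = character(0)))
  }
  out$adj_p <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "overlap", "set_size", "list_size",
               "universe_size", "p_value", "adj_p", "overlap_genes")]
  if (p_thresh < 1) out <- out[out$p_value < p_thresh, , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}
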