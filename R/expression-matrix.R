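#' Two-group expression matrix
#'
#' Light container for a log2-scale expression matrix (features x samples)
#' together with a two-group sample design. This is the common input of the
#' differential-expression screen; values are assumed pre-normalised (the
#' package's quantile normalisation is offered as a convenience, see
#' [quantile_normalize()]).
#'
#' @param values numeric matrix, features in rows and samples in columns, on
#'   the log2 scale. Row names are feature identifiers (duplicates allowed
#'   until [collapse_duplicates()] is applied), column names are sample ids.
#' @param group character or factor of length `ncol(values)` with values
#'   `"case"` and `"control"`; both groups must be non-empty.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `group` (a factor with levels `control`, `case`).
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' expression_matrix(m, c("case", "case", "case", "control", "control"))
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_invalid("`values` must be a numeric matrix")
  }
  if (any(!is.finite(values))) abort_invalid("`values` must be finite")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("F%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%04d", seq_len(ncol(values)))
  }
  group <- as.character(group)
  if (length(group) != ncol(values)) {
    abort_invalid("`group` must have one label per sample (column)")
  }
  if (!all(group %in% c("case", "control"))) {
    abort_invalid("`group` labels must be 'case' or 'control'")
  }
  if (length(unique(group)) != 2L) abort_invalid("both groups must be non-empty")
  structure(list(values = values,
                 group = factor(group, levels = c("control", "case"))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Write / read a two-group expression matrix as plain TSV
#'
#' The TSV dialect has a two-line header: line 1 holds `feature_id` followed
#' by the sample ids, line 2 holds `group` followed by the per-sample group
#' labels. Every following line is one feature row.
#'
#' @param x an [expression_matrix()].
#' @param path file path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns an `expr_matrix`.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x$values)), collapse = "\t"), con)
  writeLines(paste(c("group", as.character(x$group)), collapse = "\t"), con)
  utils::write.table(x$values, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  header <- readLines(path, n = 2L)
  samples <- strsplit(header[1L], "\t", fixed = TRUE)[[1L]][-1L]
  groups <- strsplit(header[2L], "\t", fixed = TRUE)[[1L]][-1L]
  tab <- utils::read.table(path, sep = "\t", skip = 2L, header = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(values) <- list(tab[[1L]], samples)
  expression_matrix(values, groups)
}

#' Write / read a simplified GEO-series-matrix expression file
#'
#' Emulates the layout of a processed GEO series matrix: metadata lines are
#' prefixed with `!`, the expression table is delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`, and the sample
#' group labels travel in a `!Sample_group` metadata line. Only this
#' simplified dialect is supported; no attempt is made to parse real GEO
#' annotation blocks.
#'
#' @inheritParams write_expression_tsv
#' @param seed optional integer echoed into the file header for provenance.
#' @return `write_series_matrix()` returns `path` invisibly;
#'   `read_series_matrix()` returns an `expr_matrix`.
#' @export
write_series_matrix <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!Series_title\tsynthetic two-group expression series", con)
  if (!is.null(seed)) writeLines(sprintf("!Series_seed\t%d", as.integer(seed)), con)
  writeLines(paste(c("!Sample_id", colnames(x$values)), collapse = "\t"), con)
  writeLines(paste(c("!Sample_group", as.character(x$group)), collapse = "\t"), con)
  writeLines("!series_matrix_table_begin", con)
  writeLines(paste(c("ID_REF", colnames(x$values)), collapse = "\t"), con)
  utils::write.table(x$values, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' @rdname write_series_matrix
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  grp_line <- grep("^!Sample_group\t", lines, value = TRUE)
  if (length(grp_line) != 1L) {
    stop("series matrix is missing a single '!Sample_group' line")
  }
  groups <- strsplit(grp_line, "\t", fixed = TRUE)[[1L]][-1L]
  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("series matrix table delimiters not found")
  }
  body <- lines[(begin + 1L):(end - 1L)]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(body[-1L], "\t", fixed = TRUE)
  values <- do.call(rbind, lapply(cells, function(r) as.numeric(r[-1L])))
  dimnames(values) <- list(vapply(cells, `[[`, "", 1L), header[-1L])
  expression_matrix(values, groups)
}

#' Read an expression matrix, sniffing the format
#'
#' @param path file path to a plain TSV (see [write_expression_tsv()]) or a
#'   simplified series-matrix file (see [write_series_matrix()]).
#' @param format `"auto"` sniffs for a leading `!`; otherwise force a reader.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "series_matrix")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "!")) "series_matrix" else "tsv"
  }
  switch(format,
         tsv = read_expression_tsv(path),
         series_matrix = read_series_matrix(path))
}
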