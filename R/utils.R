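# Internal parameter validation helpers. All user-facing validation errors carry
# the "fflmotif_invalid_parameter" condition class so callers can test for them.

abort_invalid <- function(msg) {
  stop(errorCondition(msg, class = "fflmotif_invalid_parameter"))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort_invalid(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed)) abort_invalid("`seed` is required")
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed)) {
    abort_invalid("`seed` must be a single integer")
  }
  as.integer(seed)
}

# Stable key for a (role, id) node; roles never contain "|".
node_key <- function(role, id) paste(role, id, sep = "|")

# sample() without the length-1 "1:x" surprise
sample_from <- function(x, k) x[sample.int(length(x), k)]
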