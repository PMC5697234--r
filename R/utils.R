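#' @importFrom utils head tail
#' @importFrom stats median rnorm runif rpois
NULL

# Hard error with a consistent prefix so callers/tests can match on class.
sv_abort <- function(msg, ..., class = "synviz_error") {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "error", "condition")))
}

sv_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Read lines tolerating a missing trailing newline; never warns.
sv_read_lines <- function(path) {
  if (!file.exists(path)) sv_abort("file not found: %s", path)
  readLines(path, warn = FALSE)
}

# Format a real so that write/read round-trips within 1e-9 relative tolerance
# and output is byte-deterministic.
sv_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) return("NA")
    if (is.finite(v) && v == floor(v) && abs(v) < 2147483647) sprintf("%d", as.integer(v))
    else sprintf("%.10g", v)
  }, character(1))
}

# Deterministic child seed derivation, kept below 2^31.
sv_child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
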