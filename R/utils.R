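# Internal helpers shared across modules.

# Nearest-rank index for a lower-tail fraction q of n items: the number of
# items in the lowest q fraction, rounded to the nearest integer.
nearest_rank_count <- function(n, q) {
  as.integer(round(n * q))
}

# Stable ascending rank: ties broken by original order.
stable_rank <- function(x) {
  rank(x, ties.method = "first")
}

# log2 with an explicit guard; callers are expected to have added any
# pseudocount already.
log2_safe <- function(x) {
  ifelse(x > 0, log2(x), -Inf)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# Format counts of skipped/clipped features for structured logging.
log_attrition <- function(what, n, quiet = TRUE) {
  if (!quiet && n > 0) inform(sprintf("%s: %d feature(s)", what, n))
  invisible(n)
}
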