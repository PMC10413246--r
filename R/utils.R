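## internal helpers shared across stages

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible per-stage seed from one global seed so that stages
## draw from independent substreams. Kept strictly below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2017L + (h %% 99991L)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

## sample() without the length-1 surprise (sample(5L) != sample of c(5L))
sample_vec <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## cached index triples for ordered-subsequence enumeration
.tri_cache <- new.env(parent = emptyenv())

tri_indices <- function(n) {
  key <- as.character(n)
  if (!is.null(.tri_cache[[key]])) return(.tri_cache[[key]])
  idx <- if (n < 3L) matrix(integer(0), nrow = 3L) else utils::combn(n, 3L)
  .tri_cache[[key]] <- idx
  idx
}
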