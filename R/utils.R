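# Internal helpers shared across modules.

# Deterministic 31-bit hash of (seed, ...) used to derive independent-looking
# RNG substreams, e.g. per (seed, participant, task). Exact integer arithmetic
# stays below 2^53 so the result is reproducible across platforms.
substream_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), unlist(lapply(list(...), as.character))),
               collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample() without the length-1 surprise
sample_from <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Moore-Penrose pseudo-inverse via SVD; used where a winsorized covariance
# can be singular (e.g. constant data).
pinv <- function(x, tol = 1e-12) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
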