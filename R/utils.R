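#' @importFrom rlang abort warn .data
#' @importFrom stats median p.adjust pbinom dbinom rexp runif rgeom ks.test
#'   wilcox.test rbinom integrate
#' @importFrom utils head combn
NULL

# Deterministic 31-adic string hash folded with the master seed; used to give
# every (stage, entity) pair its own reproducible RNG substream. Kept below
# 2^31 so it is always a valid R integer seed.
substream_seed <- function(master_seed, key) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(paste0(key))) h <- (h * 31 + ch) %% m
  as.integer((h + (master_seed %% m) * 48271) %% m)
}

# Run `code` under a seed without disturbing the caller's RNG state; a NULL
# seed means "use the current stream".
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

assert_scores <- function(scores, what = "scores") {
  if (length(scores) < 1L) {
    abort(sprintf("`%s` must contain at least one game.", what))
  }
  if (anyNA(scores) || any(scores < 0)) {
    abort(sprintf("`%s` must be non-negative and free of missing values.", what))
  }
  invisible(scores)
}
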