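#' Derive a named substream seed from a root seed
#'
#' All stochastic stages of the pipeline draw their RNG state from a single
#' root seed fanned out to named substreams, so individual stages can be
#' re-run in isolation and still reproduce exactly. The substream seed is a
#' deterministic 31-bit hash of the root seed and the label path, e.g.
#' `substream_seed(7, "field", 3)` for the third imaging field of a well.
#'
#' @param root integer root seed.
#' @param ... labels (coerced to character) naming the substream.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(root, ...) {
  labels <- paste(c(format(root, scientific = FALSE), vapply(list(...), as.character, "")),
                  collapse = "/")
  h <- as.double(root %% 2147483647)
  for (code in utf8ToInt(labels)) {
    # 31-bit multiplicative hash; constants from Park-Miller / FNV folklore
    h <- (h * 16807 + code * 2654435.0 + 1) %% 2147483629
  }
  as.integer(h %% 2147483645 + 1)
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_substream <- function(root, ..., code) {
  seed <- substream_seed(root, ...)
  withr::with_seed(seed, code)
}
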