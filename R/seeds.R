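#' Derive a reproducible substream seed
#'
#' Deterministically maps a master seed and a stream name (plus an optional
#' replicate index) to an integer seed below 2^31. Every stochastic stage of
#' the pipeline draws its seed through this function, so changing the
#' replicate count of one stage never perturbs another.
#'
#' @param seed master integer seed.
#' @param name character stream name (e.g. `"null_nodf"`).
#' @param index optional replicate index within the stream.
#' @return a positive integer scalar < 2^31.
#' @export
#' @examples
#' substream_seed(42, "robustness")
#' substream_seed(42, "robustness", 3)
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 %% 2147483647
  out <- (s + h * 7919 + as.numeric(index) * 104729) %% 2147483646
  as.integer(out + 1)
}
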