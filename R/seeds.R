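#' Derive a reproducible substream seed
#'
#' A master seed spawns named substreams (clinical, biomarker, outcome,
#' creatinine, missingness, imputation, bootstrap resamples ...) so that
#' toggling one stage of a simulation does not shift the random numbers used
#' by another. The derivation is a small multiplicative hash kept below
#' `2^31` so the result is always a valid R seed.
#'
#' @param seed master integer seed.
#' @param name character label of the substream.
#' @param index optional integer index (e.g. bootstrap replicate number).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003L
  s <- (abs(as.numeric(seed)) %% 65011) * 33013 + h * 7 + as.numeric(index) * 97
  as.integer(s %% 2147483647)
}

with_substream <- function(seed, name, index = 0L, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name, index))
  expr
}
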