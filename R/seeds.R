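#' Derive a reproducible sub-seed
#'
#' All stochastic stages take an explicit integer seed; stages that need
#' several independent RNG streams derive sub-seeds from one master seed and
#' a text tag, so a single integer determines every draw in a run while
#' distinct stages never share a stream. The derivation is a small
#' polynomial hash kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stream (e.g. `"counts_dna"`,
#'   `"run_17"`).
#' @return A non-negative integer seed < 2^31.
#' @export
derive_seed <- function(seed, tag) {
  h <- as.double(abs(as.integer(seed))) %% 2147483629
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
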