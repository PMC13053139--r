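#' Total-sum scaling (relative abundance)
#'
#' Divides each sample row by its total so rows sum to 1, making samples with
#' different sequencing depths directly comparable. A sample with zero total
#' carries no compositional information and is a hard error — silently
#' dropping it would corrupt downstream designs.
#'
#' @param m raw-layer [abundance_matrix()] with positive row totals.
#' @return An `abund_mat` with `normalisation = "tss"`.
#' @export
tss_normalise <- function(m) {
  stopifnot(inherits(m, "abund_mat"))
  if (m$normalisation != "raw") stop("tss_normalise expects a raw-layer matrix")
  rs <- rowSums(m$values)
  if (any(rs <= 0)) {
    bad <- rownames(m$values)[rs <= 0]
    stop("zero-total sample row(s): ", paste(bad, collapse = ", "))
  }
  abundance_matrix(m$values / rs, layer = m$layer, normalisation = "tss")
}

#' Hellinger transformation
#'
#' Square root of relative abundance: entry <- sqrt(value / row total).
#' Tempers the dominance of highly abundant taxa before Bray-Curtis. Because
#' it works on within-row proportions it gives the same result on raw counts
#' as on TSS-scaled data.
#'
#' @param m raw- or tss-layer [abundance_matrix()], non-negative.
#' @return An `abund_mat` with `normalisation = "hellinger"`.
#' @export
hellinger_transform <- function(m) {
  stopifnot(inherits(m, "abund_mat"))
  if (!m$normalisation %in% c("raw", "tss"))
    stop("hellinger_transform expects a raw or tss matrix")
  rs <- rowSums(m$values)
  if (any(rs <= 0)) {
    bad <- rownames(m$values)[rs <= 0]
    stop("zero-total sample row(s): ", paste(bad, collapse = ", "))
  }
  abundance_matrix(sqrt(m$values / rs), layer = m$layer,
                   normalisation = "hellinger")
}

#' Centered log-ratio transform
#'
#' Maps each composition to unconstrained real space:
#' entry <- ln(value + pseudocount) - row mean of ln(value + pseudocount),
#' so every row sums to zero. With `pseudocount = 0` the transform is
#' invariant to rescaling a row by a positive constant, the defining property
#' of a log-ratio coordinate system; the default pseudocount of 1 handles the
#' zeros ubiquitous in count data.
#'
#' @param m raw-layer [abundance_matrix()].
#' @param pseudocount non-negative offset added before taking logs; must be
#'   positive when zeros are present.
#' @return An `abund_mat` with `normalisation = "clr"`.
#' @export
clr_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "abund_mat"))
  if (m$normalisation != "raw") stop("clr_transform expects a raw-layer matrix")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount <= 0 && any(m$values == 0))
    stop("zeros present: clr_transform needs a positive pseudocount")
  lg <- log(m$values + pseudocount)
  out <- lg - rowMeans(lg)
  abundance_matrix(out, layer = m$layer, normalisation = "clr")
}

#' Min-max scale environmental predictors to [0, 1]
#'
#' Per variable, x <- (x - min) / (max - min), so heterogeneous sonde
#' variables (temperature in deg C, conductivity in uS/cm, fluorescence in
#' RFU...) enter the chain-graph on a common scale. A constant variable is
#' mapped to all zeros with a warning rather than dividing by zero.
#'
#' @param env numeric matrix or data.frame, samples in rows, variables in
#'   columns; all values finite.
#' @return Numeric matrix of the same shape with each column in \[0, 1\].
#' @export
minmax_scale <- function(env) {
  v <- as.matrix(env)
  if (!is.numeric(v)) stop("environmental values must be numeric")
  if (any(!is.finite(v))) stop("non-finite environmental value")
  out <- apply(v, 2, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  })
  out <- matrix(out, nrow = nrow(v), dimnames = dimnames(v))
  const <- apply(v, 2, function(x) max(x) == min(x))
  if (any(const))
    warning("constant variable(s) mapped to 0: ",
            paste(colnames(v)[const], collapse = ", "))
  out
}
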