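# Featured Raman extraction: restrict spectra to the crocin band windows,
# and VIP (variable influence on projection) scores to audit/reproduce the
# window choice on synthetic data.

#' Featured Raman band windows
#'
#' Inclusive wavenumber intervals; the defaults are the four crocin band
#' windows 1000--1050, 1130--1240, 1270--1300 and 1500--1580 cm^-1 that
#' cover the main compounds behind saffron's color expression. Windows must
#' be non-overlapping and ordered.
#'
#' @param windows List of length-2 numeric vectors `c(lo, hi)` in cm^-1.
#' @return A list of class `band_windows`.
#' @export
band_windows <- function(windows = list(c(1000, 1050), c(1130, 1240),
                                        c(1270, 1300), c(1500, 1580))) {
  for (w in windows) {
    if (length(w) != 2 || w[1] > w[2])
      stop("each window must be c(lo, hi) with lo <= hi")
  }
  los <- vapply(windows, `[`, numeric(1), 1)
  his <- vapply(windows, `[`, numeric(1), 2)
  o <- order(los)
  if (any(his[o][-length(o)] >= los[o][-1]))
    stop("band windows must not overlap")
  structure(windows, class = "band_windows")
}

#' Extract featured Raman variables by band windowing
#'
#' Concatenates the in-window intensities (window order, then ascending
#' wavenumber) with no resampling. On the default 1 cm^-1 grid spanning
#' 100--2200 cm^-1 the default windows give 51 + 111 + 31 + 81 = 274
#' variables.
#'
#' @param x A `raman_spectrum`, a numeric intensity vector, or an intensity
#'   matrix (rows = spectra) with wavenumber column names.
#' @param windows A [band_windows()] object.
#' @param wavenumbers Grid, required when `x` is a plain vector.
#' @return A named numeric vector (names = wavenumbers), or a matrix when
#'   `x` is a matrix.
#' @export
extract_raman_bands <- function(x, windows = band_windows(),
                                wavenumbers = NULL) {
  if (inherits(x, "raman_spectrum")) {
    wavenumbers <- x$wavenumbers
    x <- x$intensities
  }
  if (is.matrix(x)) {
    if (is.null(wavenumbers)) wavenumbers <- as.numeric(colnames(x))
  } else if (is.null(wavenumbers)) {
    stop("wavenumbers must be supplied for a plain intensity vector")
  }
  span <- range(wavenumbers)
  idx <- integer(0)
  for (w in windows) {
    if (w[1] < span[1] || w[2] > span[2])
      stop("band window [", w[1], ", ", w[2], "] outside the spectral range")
    idx <- c(idx, which(wavenumbers >= w[1] & wavenumbers <= w[2]))
  }
  if (is.matrix(x)) {
    out <- x[, idx, drop = FALSE]
    colnames(out) <- wavenumbers[idx]
  } else {
    out <- x[idx]
    names(out) <- wavenumbers[idx]
  }
  out
}

#' Variable influence on projection (VIP) scores
#'
#' Standard chemometrics VIP for a fitted PLS model:
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )`,
#' where `SSY_a` is the Y-variance explained by component `a` and `w_a` the
#' corresponding X-weight vector. The scores satisfy `sum(VIP^2) = p`, so a
#' VIP above 1 marks an above-average contributor.
#'
#' @param model A fitted [fit_pls()]/[fit_plsda()] model.
#' @return Numeric vector of `p` non-negative VIP scores (named by
#'   variable).
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "pls_model")) stop("model must be a fitted pls_model")
  W <- model$weights
  ssy <- model$ssy
  if (is.null(W) || model$ncomp < 1) stop("model has no fitted components")
  tot <- sum(ssy)
  if (tot <= 0) stop("model explains no Y-variance; VIP undefined")
  p <- nrow(W)
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  vip <- sqrt(p * as.vector(Wn^2 %*% ssy) / tot)
  names(vip) <- rownames(W)
  vip
}

#' Select variables by VIP threshold
#'
#' @param model A fitted PLS model.
#' @param threshold Scores strictly greater than this are kept (default 1,
#'   the above-average rule).
#' @return Integer indices, ascending.
#' @export
select_variables_vip <- function(model, threshold = 1) {
  which(compute_vip(model) > threshold)
}
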