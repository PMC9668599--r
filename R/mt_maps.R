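#' Sum gradient-echo volumes across echoes
#'
#' Multi-echo FLASH magnitude volumes are summed voxelwise to raise SNR before
#' any ratio or model inversion is computed; for N echoes with comparable
#' signal this improves ROI-level SNR by roughly sqrt(N).
#'
#' @param echoes a list of numeric arrays with identical dimensions (or a
#'   single array, returned unchanged).
#' @return A numeric array: the voxelwise sum.
#' @examples
#' e <- list(array(2, c(2, 2, 2)), array(3, c(2, 2, 2)), array(5, c(2, 2, 2)))
#' sum_echoes(e)[1, 1, 1]  # 10
#' @export
sum_echoes <- function(echoes) {
  if (is.numeric(echoes)) return(echoes)
  if (!is.list(echoes) || length(echoes) < 1L)
    stop("'echoes' must be a non-empty list of volumes")
  d <- dim(echoes[[1]]) %||% length(echoes[[1]])
  for (e in echoes[-1]) {
    if (!identical(dim(e) %||% length(e), d))
      stop("echo volumes have mismatched dimensions")
  }
  Reduce(`+`, echoes)
}

#' Magnetisation transfer ratio map
#'
#' \eqn{MTR = 100 (S_{off} - S_{on}) / S_{off}}, in percent. Voxels whose
#' MT_off signal is at or below \code{eps} (air, background) are flagged
#' invalid as \code{NaN} rather than clamped, so that downstream ROI
#' statistics exclude them.
#'
#' @param s_on,s_off echo-summed MT_on and MT_off volumes (same dimensions).
#' @param eps positivity guard for the denominator.
#' @return MTR volume in percent; invalid voxels are \code{NaN}.
#' @examples
#' compute_mtr(0.5, 1)  # 50
#' @export
compute_mtr <- function(s_on, s_off, eps = 1e-12) {
  check_same_grid(s_on, s_off)
  bad <- !is.finite(s_off) | !is.finite(s_on) | s_off <= eps
  out <- 100 * (s_off - s_on) / s_off
  out[bad] <- NaN
  out
}

#' Dual-flip-angle apparent T1 and amplitude maps
#'
#' From the two non-saturated FLASH volumes (the low-flip MT_off and the
#' high-flip T1-weighted volume) the small-angle rational signal model can be
#' solved in closed form for the apparent relaxation rate and amplitude:
#' \deqn{R_1^{app} = \tfrac{1}{2}\,
#'   (S_{T1w}\alpha_2/TR_2 - S_{off}\alpha_1/TR_1) /
#'   (S_{off}/\alpha_1 - S_{T1w}/\alpha_2)}
#' \deqn{A^{app} = S_{off} S_{T1w}
#'   (TR_1\alpha_2/\alpha_1 - TR_2\alpha_1/\alpha_2) /
#'   (S_{T1w} TR_1 \alpha_2 - S_{off} TR_2 \alpha_1)}
#' The inversion is exact for signals generated by the rational model and
#' accurate to a few percent for true spoiled-gradient-echo signals in the
#' small-flip-angle regime (both flips well below ~25 degrees).
#'
#' Voxels where either estimator's denominator is non-positive (degenerate
#' flip-angle pair, background) are flagged \code{NaN}; the flag propagates
#' into MTsat.
#'
#' @param s_off echo-summed MT_off volume.
#' @param s_t1w echo-summed T1-weighted volume.
#' @param acq \code{\link{acq_params}}.
#' @return A list with volumes \code{a_app} and \code{r1_app} (1/s).
#' @export
estimate_t1_amplitude <- function(s_off, s_t1w, acq) {
  validate_acq(acq)
  check_same_grid(s_off, s_t1w)
  a1 <- acq$alpha1; a2 <- acq$alpha2
  tr1 <- acq$tr1; tr2 <- acq$tr2

  den_r1 <- s_off / a1 - s_t1w / a2
  den_a  <- s_t1w * tr1 * a2 - s_off * tr2 * a1
  bad <- !is.finite(s_off) | !is.finite(s_t1w) |
    s_off <= 0 | s_t1w <= 0 | den_r1 <= 0 | den_a <= 0

  r1_app <- 0.5 * (s_t1w * a2 / tr2 - s_off * a1 / tr1) / den_r1
  a_app  <- s_off * s_t1w * (tr1 * a2 / a1 - tr2 * a1 / a2) / den_a
  bad <- bad | !is.finite(r1_app) | !is.finite(a_app) | r1_app <= 0
  r1_app[bad] <- NaN
  a_app[bad] <- NaN
  list(a_app = a_app, r1_app = r1_app)
}

#' MT saturation map
#'
#' Per-excitation saturation of longitudinal magnetisation by the MT pulse,
#' with analytic correction for flip angle and apparent T1:
#' \deqn{\delta = (A^{app}\alpha_1 / S_{on} - 1)\, R_1^{app}\, TR_1
#'   - \alpha_1^2 / 2}
#' reported as percent (\eqn{100\,\delta}). Negative values can arise from
#' noise and are kept (not clipped); voxels with invalid inputs are
#' \code{NaN}.
#'
#' @param s_on echo-summed MT_on volume.
#' @param a_app,r1_app apparent amplitude / relaxation-rate volumes from
#'   \code{\link{estimate_t1_amplitude}}.
#' @param acq \code{\link{acq_params}}.
#' @return MTsat volume in percent.
#' @export
compute_mtsat <- function(s_on, a_app, r1_app, acq) {
  validate_acq(acq)
  check_same_grid(s_on, a_app)
  check_same_grid(s_on, r1_app)
  bad <- !is.finite(s_on) | s_on <= 0 | !is.finite(a_app) | !is.finite(r1_app)
  delta <- (a_app * acq$alpha1 / s_on - 1) * r1_app * acq$tr1 -
    acq$alpha1^2 / 2
  delta[bad] <- NaN
  100 * delta
}

#' Fit all MT parametric maps from the three FLASH acquisitions
#'
#' Convenience wrapper: sums echoes for each contrast, then computes MTR, the
#' apparent T1/amplitude maps and MTsat.
#'
#' @param mt_on,mt_off,t1w each a list of echo volumes (or a single
#'   echo-summed volume).
#' @param acq \code{\link{acq_params}}.
#' @return An object of class \code{mt_maps}: list with volumes \code{mtr}
#'   and \code{mtsat} (percent), \code{a_app}, \code{r1_app} (1/s).
#' @export
fit_mt_maps <- function(mt_on, mt_off, t1w, acq) {
  s_on  <- sum_echoes(mt_on)
  s_off <- sum_echoes(mt_off)
  s_t1w <- sum_echoes(t1w)
  t1fit <- estimate_t1_amplitude(s_off, s_t1w, acq)
  structure(list(
    mtr    = compute_mtr(s_on, s_off),
    mtsat  = compute_mtsat(s_on, t1fit$a_app, t1fit$r1_app, acq),
    a_app  = t1fit$a_app,
    r1_app = t1fit$r1_app
  ), class = "mt_maps")
}

check_same_grid <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) stop("volumes have mismatched dimensions")
  invisible(TRUE)
}
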