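#' FLASH acquisition parameters for magnetisation transfer imaging
#'
#' Container for the spoiled gradient-echo protocol used to acquire the three
#' MT-weighted volumes: the proton-density-weighted pair (MT_on / MT_off,
#' low flip angle, long TR) and the T1-weighted volume (higher flip angle,
#' short TR). Defaults correspond to a 3D FLASH protocol with 5 deg / 18 deg
#' excitation, TR 30 / 15 ms and three echoes at 1.54 / 4.55 / 8.49 ms.
#'
#' Angles are stored in radians and times in seconds; the constructor accepts
#' degrees and milliseconds because that is how protocols are written down.
#'
#' @param flip1 excitation flip angle of the MT_on / MT_off volumes (degrees).
#' @param flip2 excitation flip angle of the T1-weighted volume (degrees).
#' @param tr1 repetition time of the MT_on / MT_off volumes (ms).
#' @param tr2 repetition time of the T1-weighted volume (ms).
#' @param te echo times (ms); all three contrasts share the echo train.
#'
#' @return An object of class \code{acq_params}: a list with elements
#'   \code{alpha1}, \code{alpha2} (radians), \code{tr1}, \code{tr2}, \code{te}
#'   (seconds).
#' @examples
#' acq <- acq_params()          # the default 5/18 deg, 30/15 ms protocol
#' acq_params(flip1 = 6, flip2 = 20, tr1 = 25, tr2 = 11)
#' @export
acq_params <- function(flip1 = 5, flip2 = 18, tr1 = 30, tr2 = 15,
                       te = c(1.54, 4.55, 8.49)) {
  alpha1 <- flip1 * pi / 180
  alpha2 <- flip2 * pi / 180
  out <- list(alpha1 = alpha1, alpha2 = alpha2,
              tr1 = tr1 / 1000, tr2 = tr2 / 1000, te = te / 1000)
  validate_acq(out)
  structure(out, class = "acq_params")
}

validate_acq <- function(acq) {
  stopifnot(is.list(acq))
  with(acq, {
    if (!all(is.finite(c(alpha1, alpha2, tr1, tr2, te))))
      stop("acquisition parameters must be finite")
    if (!(alpha1 > 0 && alpha2 > alpha1 && alpha2 < pi / 2))
      stop("flip angles must satisfy 0 < alpha1 < alpha2 < 90 degrees")
    if (tr1 <= 0 || tr2 <= 0 || any(te <= 0))
      stop("repetition and echo times must be positive")
  })
  invisible(acq)
}

#' @exportS3Method base::print
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "FLASH MT protocol: flip %.1f/%.1f deg, TR %.1f/%.1f ms, %d echo(es)\n",
    x$alpha1 * 180 / pi, x$alpha2 * 180 / pi,
    x$tr1 * 1000, x$tr2 * 1000, length(x$te)))
  invisible(x)
}
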