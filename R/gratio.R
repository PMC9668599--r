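#' Myelin volume fraction from MTsat
#'
#' The aggregate g-ratio framework takes MVF as linearly scaled MTsat:
#' \code{mvf = k * mtsat}, with \code{k} in fraction per MTsat-percent,
#' calibrated on healthy-control white matter (\code{\link{calibrate_k}}).
#' Results are clipped to [0, 1]; the number of clipped voxels is attached as
#' attribute \code{"n_clipped"} and a warning is raised if any were.
#'
#' @param mtsat MTsat volume in percent.
#' @param k scaling constant (> 0), fraction per percent.
#' @return MVF volume in [0, 1] (NaN where MTsat is NaN).
#' @examples
#' compute_mvf(3.74, k = 0.1)  # 0.374
#' @export
compute_mvf <- function(mtsat, k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("'k' must be a single positive number")
  mvf <- k * mtsat
  clip <- is.finite(mvf) & (mvf < 0 | mvf > 1)
  mvf[is.finite(mvf) & mvf < 0] <- 0
  mvf[is.finite(mvf) & mvf > 1] <- 1
  if (any(clip)) warning(sum(clip), " MVF voxel(s) clipped to [0,1]")
  attr(mvf, "n_clipped") <- sum(clip)
  mvf
}

#' Axonal volume fraction from NODDI fractions and MVF
#'
#' \code{avf = (1 - mvf) * (1 - isovf) * icvf}: the intra-neurite fraction of
#' the non-myelin, non-free-water voxel volume.
#'
#' @param mvf myelin volume fraction volume in [0, 1].
#' @param isovf NODDI isotropic (free-water) volume fraction in [0, 1].
#' @param icvf NODDI intra-neurite (restricted) volume fraction in [0, 1].
#' @return AVF volume in [0, 1].
#' @examples
#' compute_avf(0.25, 0.1, 0.6)  # 0.405
#' @export
compute_avf <- function(mvf, isovf, icvf) {
  for (x in list(mvf = mvf, isovf = isovf, icvf = icvf)) {
    v <- x[is.finite(x)]
    if (any(v < 0 | v > 1)) stop("volume fractions must lie in [0, 1]")
  }
  (1 - mvf) * (1 - isovf) * icvf
}

#' Aggregate MRI g-ratio
#'
#' \deqn{g = \sqrt{AVF / (AVF + MVF)} = \sqrt{1 / (1 + MVF/AVF)}}
#' the ratio of inner axonal to outer myelinated-fibre diameter implied by
#' the voxel's myelin and axon volume fractions. Unmyelinated tissue
#' (MVF = 0, AVF > 0) gives g = 1; voxels with AVF <= 0 are undefined and
#' flagged \code{NaN}.
#'
#' @param mvf,avf myelin / axonal volume fraction volumes.
#' @return g-ratio volume in (0, 1]; NaN where undefined.
#' @examples
#' compute_gratio(0.25, 0.25)   # sqrt(0.5) = 0.7071
#' compute_gratio(0, 0.4)       # 1
#' @export
compute_gratio <- function(mvf, avf) {
  check_same_grid(mvf, avf)
  g <- sqrt(avf / (avf + mvf))
  g[!is.finite(avf) | !is.finite(mvf) | avf <= 0] <- NaN
  g
}

#' Calibrate the MVF scaling constant on healthy-control white matter
#'
#' Finds \code{k} such that the mean g-ratio over pooled control
#' white-matter voxels equals \code{g_target}. The mean g is continuous and
#' strictly decreasing in \code{k} (below MVF clipping), so a 1-D root find
#' over \code{interval} suffices; the root is located to |mean g - target|
#' below \code{tol}.
#'
#' @param mtsat,icvf,isovf lists (one element per control scan) of MTsat
#'   (percent), ICVF and ISOVF volumes.
#' @param masks list of logical white-matter masks, same order/grids.
#' @param g_target target mean white-matter g-ratio (default 0.581, a typical
#'   healthy-control white-matter value for this calibration style).
#' @param interval search bracket for \code{k} (fraction per percent).
#' @param tol tolerance on the achieved mean g.
#' @return A list: \code{k}, \code{g_achieved}, \code{n_voxels},
#'   \code{g_target}.
#' @export
calibrate_k <- function(mtsat, icvf, isovf, masks, g_target = 0.581,
                        interval = c(1e-4, 1), tol = 1e-9) {
  if (!is.list(mtsat)) mtsat <- list(mtsat)
  if (!is.list(icvf))  icvf  <- list(icvf)
  if (!is.list(isovf)) isovf <- list(isovf)
  if (!is.list(masks)) masks <- list(masks)
  n <- length(mtsat)
  if (n < 1L || length(icvf) != n || length(isovf) != n ||
      length(masks) != n)
    stop("need equal-length lists of MTsat, ICVF, ISOVF and masks")
  if (!is.numeric(g_target) || g_target <= 0 || g_target >= 1)
    stop("'g_target' must lie in (0, 1)")

  grab <- function(vol, m) vol[m]
  ms <- unlist(mapply(grab, mtsat, masks, SIMPLIFY = FALSE))
  iv <- unlist(mapply(grab, icvf,  masks, SIMPLIFY = FALSE))
  sv <- unlist(mapply(grab, isovf, masks, SIMPLIFY = FALSE))
  ok <- is.finite(ms) & is.finite(iv) & is.finite(sv)
  ms <- ms[ok]; iv <- iv[ok]; sv <- sv[ok]
  if (length(ms) == 0L) stop("no valid white-matter voxels to calibrate on")

  # in the calibration objective the fully-myelinated limit (AVF -> 0 with
  # MVF > 0) contributes g = 0, keeping the objective defined and monotone
  mean_g <- function(k) {
    mvf <- pmin(pmax(k * ms, 0), 1)
    avf <- compute_avf(mvf, sv, iv)
    g <- compute_gratio(mvf, avf)
    g[avf <= 0 & mvf > 0] <- 0
    mean(g, na.rm = TRUE)
  }
  flo <- mean_g(interval[1]) - g_target
  fhi <- mean_g(interval[2]) - g_target
  if (flo * fhi > 0)
    stop("g_target ", g_target, " not attainable over the k bracket [",
         interval[1], ", ", interval[2], "]")
  root <- uniroot(function(k) mean_g(k) - g_target,
                  interval = interval, tol = tol * 1e-2)
  k <- root$root
  g_ach <- mean_g(k)
  if (abs(g_ach - g_target) > max(tol, 1e-6))
    warning("calibration achieved |mean g - target| = ",
            format(abs(g_ach - g_target)))
  list(k = k, g_achieved = g_ach, n_voxels = length(ms),
       g_target = g_target)
}

#' g-ratio maps from MTsat and NODDI inputs
#'
#' Chains \code{\link{compute_mvf}}, \code{\link{compute_avf}} and
#' \code{\link{compute_gratio}} for a single scan.
#'
#' @param mtsat MTsat volume (percent).
#' @param icvf,isovf NODDI volume-fraction maps.
#' @param k MVF scaling constant (see \code{\link{calibrate_k}}).
#' @return List of volumes \code{mvf}, \code{avf}, \code{g}.
#' @export
fit_gratio_maps <- function(mtsat, icvf, isovf, k) {
  mvf <- suppressWarnings(compute_mvf(mtsat, k))
  avf <- compute_avf(mvf, isovf, icvf)
  list(mvf = mvf, avf = avf, g = compute_gratio(mvf, avf))
}
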