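#' Binary erosion of a 3-D mask
#'
#' Morphological erosion with a 3x3x3 box structuring element
#' (26-connectivity): a voxel survives only if its full neighbourhood lies
#' inside the mask. Voxels outside the array are treated as background, so
#' the mask also erodes at the volume boundary. Applied to normal-appearing
#' white-matter masks to limit partial-volume contamination at tissue edges.
#'
#' @param mask logical (or 0/1) 3-D array.
#' @param iterations number of one-voxel erosions (default 1).
#' @return Logical array of the same dimensions.
#' @examples
#' cube <- array(TRUE, c(3, 3, 3))
#' sum(erode_mask(cube))  # 1: only the centre survives
#' @export
erode_mask <- function(mask, iterations = 1) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3-D array")
  m <- array(as.logical(mask), dim(mask))
  if (anyNA(m)) stop("'mask' must be binary with no missing values")
  for (i in seq_len(iterations)) m <- erode_once(m)
  if (!any(m)) warning("erosion produced an empty mask")
  m
}

erode_once <- function(m) {
  d <- dim(m)
  out <- m
  idx <- function(n, s) {            # source indices for shift by s, padded FALSE
    if (s == 0) seq_len(n) else if (s == 1) c(seq_len(n)[-1], NA) else
      c(NA, seq_len(n)[-n])
  }
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- m[idx(d[1], dx), idx(d[2], dy), idx(d[3], dz), drop = FALSE]
    sh[is.na(sh)] <- FALSE
    out <- out & sh
  }
  out
}

#' Summary statistics of a parametric map over a region of interest
#'
#' Mean, median, SD and voxel count over \code{mask}, after removing voxels
#' in \code{exclusion} (if given) and voxels flagged invalid (\code{NA}/
#' \code{NaN}) by the mapping stage.
#'
#' @param map numeric volume.
#' @param mask logical ROI volume, same grid.
#' @param exclusion optional logical volume of voxels to drop (e.g. a
#'   cerebellum mask for diffusion-derived metrics).
#' @return A one-row data.frame: \code{mean}, \code{median}, \code{sd},
#'   \code{n_voxels}.
#' @export
summarise_region <- function(map, mask, exclusion = NULL) {
  check_same_grid(map, mask)
  m <- as.logical(mask)
  if (!is.null(exclusion)) {
    check_same_grid(map, exclusion)
    m <- m & !as.logical(exclusion)
  }
  v <- map[m]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty region after exclusions")
  data.frame(mean = mean(v), median = median(v),
             sd = if (length(v) > 1L) sd(v) else 0,
             n_voxels = length(v))
}

#' Brain parenchymal fraction
#'
#' Whole-brain tissue volume (including white-matter lesions) divided by
#' intracranial volume; a normalised atrophy marker. Computed from voxel
#' counts (voxel volume cancels on a shared grid).
#'
#' @param brain logical brain-tissue mask (must include lesion voxels).
#' @param icv logical intracranial-volume mask; must contain \code{brain}.
#' @return BPF in (0, 1].
#' @examples
#' icv <- array(TRUE, c(10, 10, 15))
#' brain <- icv; brain[, , 1:3] <- FALSE
#' compute_bpf(brain, icv)  # 0.8
#' @export
compute_bpf <- function(brain, icv) {
  check_same_grid(brain, icv)
  b <- as.logical(brain); v <- as.logical(icv)
  if (!any(v)) stop("empty intracranial mask")
  if (any(b & !v)) stop("brain mask extends outside the intracranial mask")
  sum(b) / sum(v)
}

#' Long-format ROI summary table for a cohort
#'
#' Applies the region definitions of the study design to every scan:
#' normal-appearing white matter is the white-matter mask minus the lesion
#' mask, eroded by one voxel; lesions are summarised as supplied; healthy
#' controls contribute a single eroded white-matter region. Diffusion-derived
#' metrics (ICVF, ISOVF, g-ratio) exclude the cerebellum. One row per
#' subject x timepoint x region x metric, plus the scan's brain parenchymal
#' fraction as a column.
#'
#' @param cohort an \code{mt_cohort} from \code{\link{generate_cohort}}.
#' @param maps nested list \code{maps[[subject]][[timepoint]]}, each holding
#'   volumes named \code{mtsat}, \code{mtr}, \code{icvf}, \code{isovf},
#'   \code{g} (any subset).
#' @param erode_iterations NAWM/WM erosion depth in voxels.
#' @return data.frame with columns subject, arm, timepoint, region, metric,
#'   mean, median, sd, n_voxels, bpf.
#' @export
build_cohort_table <- function(cohort, maps, erode_iterations = 1) {
  stopifnot(inherits(cohort, "mt_cohort"))
  dmri_metrics <- c("icvf", "isovf", "g")
  rows <- list()
  for (sid in names(maps)) {
    arm <- cohort$meta$arm[match(sid, cohort$meta$subject)]
    msk <- cohort$masks[[sid]]
    bpf <- compute_bpf(msk$brain, msk$icv)
    for (tp in names(maps[[sid]])) {
      wml <- if (is.list(msk$wml)) msk$wml[[tp]] else msk$wml
      wm_core <- msk$wm & !wml
      nawm <- suppressWarnings(erode_mask(wm_core, erode_iterations))
      if (!any(nawm)) stop("eroded NAWM empty for subject ", sid)
      regions <- if (arm == "control") list(wm = nawm) else
        list(nawm = nawm, wml = wml)
      mp <- maps[[sid]][[tp]]
      for (rg in names(regions)) {
        if (!any(regions[[rg]])) next
        for (metric in names(mp)) {
          if (is.null(mp[[metric]])) next
          excl <- if (metric %in% dmri_metrics) msk$cereb else NULL
          s <- summarise_region(mp[[metric]], regions[[rg]], excl)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sid, arm = arm, timepoint = tp, region = rg,
            metric = metric, s, bpf = bpf)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
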