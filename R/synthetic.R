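#' Default tissue parameter distributions per region
#'
#' Region-level means and between-subject SDs for the quantities the
#' generator controls directly: MTsat (percent), NODDI ICVF and ISOVF, and
#' the target MTR (percent) from which the apparent R1 is derived under the
#' rational signal model (\code{\link{r1_for_mtr}}). Values represent healthy
#' control white matter ("wm"), patient normal-appearing white matter
#' ("nawm") and white-matter lesions ("wml") in a recently diagnosed RRMS
#' cohort; patient between-subject SDs are set to a quarter of the cohort
#' range, control SDs to the reported cross-sectional SD.
#'
#' @return data.frame keyed by region with columns \code{mtsat}, \code{mtsat_sd},
#'   \code{icvf}, \code{icvf_sd}, \code{isovf}, \code{isovf_sd}, \code{mtr},
#'   \code{a}, \code{a_sd}.
#' @export
region_defaults <- function() {
  data.frame(
    region   = c("wm", "nawm", "wml"),
    mtsat    = c(3.74, 3.80, 2.35),
    mtsat_sd = c(0.13, 0.16, 0.32),
    icvf     = c(0.605, 0.577, 0.379),
    icvf_sd  = c(0.022, 0.034, 0.046),
    isovf    = c(0.086, 0.075, 0.095),
    isovf_sd = c(0.008, 0.011, 0.037),
    mtr      = c(54.51, 54.25, 47.33),
    mtr_sd   = c(0.66, 1.37, 2.30),
    a        = c(0.70, 0.70, 0.75),
    a_sd     = c(0.03, 0.03, 0.03),
    row.names = c("wm", "nawm", "wml"))
}

#' Default annual change per metric and patient region
#'
#' Ground-truth one-year effects applied to patient tissue parameters at the
#' follow-up timepoint. MTsat falls slightly in normal-appearing white matter
#' (subtle demyelination) and rises in lesions (remyelination); ICVF rises in
#' both; free water rises in lesions. The MTR trajectory is prescribed
#' directly (default: no true change): R1 is co-adjusted with the MTsat shift
#' — T1 prolongation accompanies demyelination — so that MTR follows its own
#' target rather than passively tracking MTsat.
#'
#' @return data.frame keyed by patient region with columns \code{mtsat},
#'   \code{icvf}, \code{isovf}, \code{mtr} (annual additive changes).
#' @export
effect_defaults <- function() {
  data.frame(
    region = c("nawm", "wml"),
    mtsat  = c(-0.03, 0.08),
    icvf   = c(0.002, 0.021),
    isovf  = c(0.000, 0.010),
    mtr    = c(0, 0),
    row.names = c("nawm", "wml"))
}

#' Default scan-rescan (session) noise SDs at the ROI level
#'
#' SD of the subject-level perturbation applied to each tissue parameter at
#' every session, per region. Chosen so that the SD of test-retest
#' differences of ROI means (sqrt(2) times these values) matches the
#' healthy-control Bland-Altman difference SDs for white matter, and the
#' patient difference SDs for lesions; the R1 session SD is set so the
#' implied MTR difference SD lands on its reported scale.
#'
#' @return data.frame keyed by region: \code{mtsat} (percent), \code{icvf},
#'   \code{isovf}, \code{r1} (1/s).
#' @export
session_sd_defaults <- function() {
  s2 <- sqrt(2)
  data.frame(
    region = c("wm", "nawm", "wml"),
    mtsat  = c(0.09, 0.09, 0.10) / s2,
    icvf   = c(0.003, 0.003, 0.020) / s2,
    isovf  = c(0.003, 0.003, 0.017) / s2,
    r1     = c(0.0097, 0.0097, 0.005),
    row.names = c("wm", "nawm", "wml"))
}

#' Configuration for the synthetic two-timepoint cohort
#'
#' Defines the simulated study: a patient arm imaged at baseline (M0) and one
#' year (M12) with prescribed annual effects, and a healthy-control arm
#' imaged twice within a short interval (test/retest, no true change). All
#' volumes are born co-registered on a single axial-slab grid (1 mm
#' isotropic); each scan comprises three-echo FLASH MT_on / MT_off / T1w
#' series plus NODDI ICVF and ISOVF maps, with masks for intracranial
#' volume, brain, white matter, lesions and a cerebellum-exclusion region.
#'
#' @param n_patients patients in the longitudinal arm (>= 2).
#' @param n_controls healthy controls in the test-retest arm (>= 2).
#' @param n_dmri_missing patients whose diffusion data are unavailable
#'   (NODDI maps omitted), as happens when dMRI processing fails.
#' @param grid volume dimensions (voxels), 1 mm isotropic.
#' @param regions region parameter table (see \code{\link{region_defaults}}).
#' @param effects annual-change table (see \code{\link{effect_defaults}}).
#' @param session_sd session-noise table (see
#'   \code{\link{session_sd_defaults}}).
#' @param voxel_noise_sd voxel noise SD on each echo image, as a fraction of
#'   the mean white-matter MT_off single-echo signal.
#' @param noddi_voxel_sd voxel noise SD on the NODDI maps (absolute).
#' @param noise_model \code{"gaussian"} (default) or \code{"rician"}.
#' @param model forward signal model, \code{"rational"} or \code{"exact"}
#'   (see \code{\link{simulate_flash_signal}}).
#' @param dmt_fraction fraction of patients who initiate disease-modifying
#'   therapy during follow-up; assigned to exactly
#'   \code{round(dmt_fraction * n_patients)} randomly chosen patients.
#' @param female_fraction fraction of female subjects (exact counts).
#' @param age_mean,age_sd,age_range age distribution (years), truncated.
#' @param lesion_load_median,lesion_load_sdlog,lesion_load_range lognormal
#'   white-matter lesion load, percent of intracranial volume.
#' @param new_lesion_fraction fraction of patients who accrue one new lesion
#'   by M12 (0 = lesion masks fixed between timepoints).
#' @param acq \code{\link{acq_params}}.
#' @param t2star effective T2* (s) governing inter-echo signal decay.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 62, n_controls = 11,
                          n_dmri_missing = 2,
                          grid = c(32, 32, 16),
                          regions = region_defaults(),
                          effects = effect_defaults(),
                          session_sd = session_sd_defaults(),
                          voxel_noise_sd = 0.02,
                          noddi_voxel_sd = 0.01,
                          noise_model = c("gaussian", "rician"),
                          model = c("rational", "exact"),
                          dmt_fraction = 38 / 62,
                          female_fraction = 48 / 62,
                          age_mean = 37.6, age_sd = 10,
                          age_range = c(21.7, 67.3),
                          lesion_load_median = 0.572,
                          lesion_load_sdlog = 0.6,
                          lesion_load_range = c(0.041, 2.628),
                          new_lesion_fraction = 0,
                          acq = acq_params(),
                          t2star = 0.05) {
  noise_model <- match.arg(noise_model)
  model <- match.arg(model)
  if (n_patients < 2 || n_controls < 2)
    stop("each arm needs at least 2 subjects")
  if (any(unlist(session_sd[, -1]) < 0) ||
      any(unlist(regions[, grepl("_sd$", names(regions))]) < 0))
    stop("SDs must be non-negative")
  if (voxel_noise_sd < 0 || noddi_voxel_sd < 0) stop("SDs must be non-negative")
  if (length(grid) != 3L || any(grid < 12))
    stop("grid must be 3-D and large enough for an eroded white-matter core")
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              n_dmri_missing = n_dmri_missing, grid = as.integer(grid),
              regions = regions, effects = effects, session_sd = session_sd,
              voxel_noise_sd = voxel_noise_sd,
              noddi_voxel_sd = noddi_voxel_sd,
              noise_model = noise_model, model = model,
              dmt_fraction = dmt_fraction,
              female_fraction = female_fraction,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              lesion_load_median = lesion_load_median,
              lesion_load_sdlog = lesion_load_sdlog,
              lesion_load_range = lesion_load_range,
              new_lesion_fraction = new_lesion_fraction,
              acq = acq, t2star = t2star)
  structure(cfg, class = "cohort_config")
}

# Template geometry shared by all subjects: nested ellipsoids on the grid.
build_geometry <- function(grid) {
  d <- grid
  ctr <- (d + 1) / 2
  ell <- function(semi) {
    x <- (seq_len(d[1]) - ctr[1]) / semi[1]
    y <- (seq_len(d[2]) - ctr[2]) / semi[2]
    z <- (seq_len(d[3]) - ctr[3]) / semi[3]
    outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
  }
  icv   <- ell(d / 2 - 1)
  brain <- ell(d / 2 - 2.5)
  wm    <- ell(pmax(d / 2 - 5, 3))
  zcut <- ctr[3] - d[3] / 8
  cereb <- brain & (slice_index(d, 3) <= zcut)
  if (!any(erode_once(wm))) stop("grid too small: eroded white matter empty")
  list(icv = icv, brain = brain, wm = wm, cereb = cereb)
}

slice_index <- function(d, axis) {
  aperm(array(seq_len(d[axis]),
              dim = d[c(axis, setdiff(1:3, axis))]),
        order(c(axis, setdiff(1:3, axis))))
}

# Spherical lesions totalling ~target_voxels inside the (eroded) white matter.
place_lesions <- function(wm, target_voxels) {
  d <- dim(wm)
  wml <- array(FALSE, d)
  # keep lesions a minority of white matter so an eroded NAWM always remains
  target_voxels <- min(target_voxels, 0.25 * sum(wm))
  if (target_voxels < 1) return(wml)
  core <- erode_once(wm)
  cand <- which(core)
  if (length(cand) == 0L) return(wml)
  xs <- slice_index(d, 1); ys <- slice_index(d, 2); zs <- slice_index(d, 3)
  guard <- 0L
  while (sum(wml) < target_voxels && guard < 50L) {
    guard <- guard + 1L
    ctr_i <- cand[sample.int(length(cand), 1L)]
    cx <- xs[ctr_i]; cy <- ys[ctr_i]; cz <- zs[ctr_i]
    r <- runif(1, 1.2, 2.4)
    sphere <- ((xs - cx)^2 + (ys - cy)^2 + (zs - cz)^2) <= r^2
    wml <- wml | (sphere & wm)
  }
  wml
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic multi-contrast cohort
#'
#' Draws subject-level tissue parameters from the configured region
#' distributions, applies the prescribed annual effects at the patient
#' follow-up timepoint (with R1 solved so that each subject's MTR follows its
#' own target trajectory), perturbs parameters per session with the
#' configured scan-rescan noise, and forward-simulates three-echo FLASH
#' signals plus NODDI maps voxel by voxel with additive noise. The same seed
#' reproduces the cohort bit for bit.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer RNG seed.
#' @return An object of class \code{mt_cohort}: list with
#'   \describe{
#'     \item{meta}{subject metadata (subject, arm, age, sex, dmt_initiated,
#'       lesion_load_pct_icv, new_lesions).}
#'     \item{scans}{\code{scans[[subject]][[timepoint]]}: lists of echo
#'       volumes \code{mt_on}, \code{mt_off}, \code{t1w} and maps
#'       \code{icvf}, \code{isovf} (NULL if dMRI missing).}
#'     \item{masks}{per subject: \code{icv}, \code{brain}, \code{wm},
#'       \code{cereb}, and per-timepoint lesion masks \code{wml}.}
#'     \item{truth}{ground-truth ROI parameters per subject, timepoint and
#'       region (before voxel noise).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  geom <- build_geometry(config$grid)

  n_p <- config$n_patients; n_c <- config$n_controls
  ids <- c(sprintf("P%03d", seq_len(n_p)), sprintf("C%03d", seq_len(n_c)))
  arm <- rep(c("patient", "control"), c(n_p, n_c))

  exact_flags <- function(n, frac) {
    k <- round(frac * n)
    sample(rep(c(TRUE, FALSE), c(k, n - k)))
  }
  sex <- ifelse(c(exact_flags(n_p, config$female_fraction),
                  exact_flags(n_c, 0.5)), "F", "M")
  dmt <- c(exact_flags(n_p, config$dmt_fraction), rep(FALSE, n_c))
  newles <- c(exact_flags(n_p, config$new_lesion_fraction), rep(FALSE, n_c))
  age <- rtrunc_norm(n_p + n_c, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  load <- c(pmin(pmax(
    exp(rnorm(n_p, log(config$lesion_load_median),
              config$lesion_load_sdlog)),
    config$lesion_load_range[1]), config$lesion_load_range[2]),
    rep(0, n_c))
  dmri_missing <- c(exact_flags(n_p, config$n_dmri_missing / n_p),
                    rep(FALSE, n_c))

  meta <- data.frame(subject = ids, arm = arm, age = age, sex = sex,
                     dmt_initiated = dmt, lesion_load_pct_icv = load,
                     new_lesions = newles, dmri_missing = dmri_missing)

  scans <- list(); masks <- list(); truth <- list()
  for (i in seq_along(ids)) {
    sid <- ids[i]
    is_pat <- arm[i] == "patient"
    tps <- if (is_pat) c("M0", "M12") else c("test", "retest")

    wml0 <- if (is_pat)
      place_lesions(geom$wm, load[i] / 100 * sum(geom$icv)) else
      array(FALSE, config$grid)
    wml1 <- wml0
    if (is_pat && newles[i]) {
      extra <- place_lesions(geom$wm & !wml0, 15)
      wml1 <- wml0 | extra
    }
    masks[[sid]] <- list(icv = geom$icv, brain = geom$brain, wm = geom$wm,
                         cereb = geom$cereb,
                         wml = setNames(list(wml0, wml1), tps))

    base <- draw_subject_params(config, is_pat)
    scans[[sid]] <- list()
    for (j in seq_along(tps)) {
      tp <- tps[j]
      par_tp <- if (is_pat && j == 2L)
        apply_effects(base, config) else base
      par_ses <- perturb_session(par_tp, config)
      sc <- simulate_scan(par_ses, geom, masks[[sid]]$wml[[tp]], config)
      if (dmri_missing[i]) sc$icvf <- sc$isovf <- NULL
      scans[[sid]][[tp]] <- sc
      for (rg in names(par_ses)) {
        p <- par_ses[[rg]]
        truth[[length(truth) + 1L]] <- data.frame(
          subject = sid, timepoint = tp, region = rg,
          mtsat = p$mtsat, r1 = p$r1, a = p$a,
          icvf = p$icvf, isovf = p$isovf,
          mtr = mtr_rational(p$mtsat / 100, p$r1, config$acq))
      }
    }
  }
  structure(list(meta = meta, scans = scans, masks = masks,
                 truth = do.call(rbind, truth), config = config),
            class = "mt_cohort")
}

# Subject-level baseline parameters for each region the subject carries.
draw_subject_params <- function(config, is_patient) {
  rgs <- if (is_patient) c("nawm", "wml") else "wm"
  out <- list()
  for (rg in rgs) {
    r <- config$regions[rg, ]
    mtsat <- rtrunc_norm(1, r$mtsat, r$mtsat_sd, lo = 0.2)
    mtr   <- rtrunc_norm(1, r$mtr, r$mtr_sd, lo = 5, hi = 90)
    out[[rg]] <- list(
      mtsat = mtsat,
      icvf  = rtrunc_norm(1, r$icvf, r$icvf_sd, 0.01, 0.99),
      isovf = rtrunc_norm(1, r$isovf, r$isovf_sd, 0.005, 0.6),
      a     = rtrunc_norm(1, r$a, r$a_sd, lo = 0.2),
      r1    = r1_for_mtr(mtr, mtsat / 100, config$acq))
  }
  out
}

# Apply the configured annual effects; R1 is re-solved so the subject's MTR
# moves by the configured MTR effect (default 0) rather than tracking MTsat.
apply_effects <- function(par, config) {
  for (rg in names(par)) {
    if (!rg %in% rownames(config$effects)) next
    ef <- config$effects[rg, ]
    p <- par[[rg]]
    mtr0 <- mtr_rational(p$mtsat / 100, p$r1, config$acq)
    p$mtsat <- p$mtsat + ef$mtsat
    p$icvf  <- min(max(p$icvf + ef$icvf, 0), 1)
    p$isovf <- min(max(p$isovf + ef$isovf, 0), 1)
    p$r1    <- r1_for_mtr(mtr0 + ef$mtr, p$mtsat / 100, config$acq)
    par[[rg]] <- p
  }
  par
}

perturb_session <- function(par, config) {
  for (rg in names(par)) {
    s <- config$session_sd[rg, ]
    p <- par[[rg]]
    p$mtsat <- max(p$mtsat + rnorm(1, 0, s$mtsat), 0.05)
    p$icvf  <- min(max(p$icvf + rnorm(1, 0, s$icvf), 0), 1)
    p$isovf <- min(max(p$isovf + rnorm(1, 0, s$isovf), 0), 1)
    p$r1    <- max(p$r1 + rnorm(1, 0, s$r1), 0.1)
    par[[rg]] <- p
  }
  par
}

# Non-WM surroundings: fixed plausible values (grey-matter band, CSF).
BACKGROUND_TISSUE <- list(
  gm  = list(mtsat = 1.8,  r1 = 0.62, a = 0.85, icvf = 0.40, isovf = 0.12),
  csf = list(mtsat = 0.05, r1 = 0.25, a = 1.00, icvf = 0.02, isovf = 0.95))

# Forward-simulate one scan: parameter fields -> echo images (+ noise).
simulate_scan <- function(par, geom, wml, config) {
  d <- config$grid
  wm_region <- names(par)[1]           # "wm" or "nawm"
  fill <- function(field) {
    v <- array(0, d)
    gm <- BACKGROUND_TISSUE$gm; csf <- BACKGROUND_TISSUE$csf
    v[geom$icv]  <- csf[[field]]
    v[geom$brain] <- gm[[field]]
    v[geom$wm]   <- par[[wm_region]][[field]]
    if (any(wml)) v[wml] <- par$wml[[field]]
    v
  }
  delta <- fill("mtsat") / 100
  r1    <- fill("r1")
  a     <- fill("a")
  icvf  <- fill("icvf")
  isovf <- fill("isovf")

  acq <- config$acq
  inside <- geom$icv
  # absolute voxel noise scale: fraction of mean WM MT_off single-echo signal
  s_ref <- simulate_flash_signal(par[[wm_region]]$a, par[[wm_region]]$r1,
                                 flip = acq$alpha1, tr = acq$tr1,
                                 model = config$model)
  sig <- config$voxel_noise_sd * s_ref

  gen_contrast <- function(flip, tr, mt_on) {
    lapply(acq$te, function(te) {
      s <- array(0, d)
      s[inside] <- simulate_flash_signal(a[inside], pmax(r1[inside], 0.05),
                                         delta = delta[inside], flip = flip,
                                         tr = tr, model = config$model,
                                         mt_on = mt_on) *
        exp(-te / config$t2star)
      add_noise(s, sig, config$noise_model)
    })
  }
  icvf_n  <- pmin(pmax(icvf  + if (config$noddi_voxel_sd > 0)
    rnorm(length(icvf), 0, config$noddi_voxel_sd) else 0, 0), 1)
  isovf_n <- pmin(pmax(isovf + if (config$noddi_voxel_sd > 0)
    rnorm(length(isovf), 0, config$noddi_voxel_sd) else 0, 0), 1)
  dim(icvf_n) <- d; dim(isovf_n) <- d

  list(mt_off = gen_contrast(acq$alpha1, acq$tr1, FALSE),
       mt_on  = gen_contrast(acq$alpha1, acq$tr1, TRUE),
       t1w    = gen_contrast(acq$alpha2, acq$tr2, FALSE),
       icvf   = icvf_n, isovf = isovf_n)
}

add_noise <- function(s, sig, model) {
  if (sig <= 0) return(s)
  n <- length(s)
  if (model == "gaussian") {
    s + array(rnorm(n, 0, sig), dim(s))
  } else {
    sqrt((s + array(rnorm(n, 0, sig), dim(s)))^2 +
           array(rnorm(n, 0, sig), dim(s))^2)
  }
}

#' @exportS3Method base::print
print.mt_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MT cohort: %d patients, %d controls, grid %s\n",
              sum(x$meta$arm == "patient"), sum(x$meta$arm == "control"),
              paste(x$config$grid, collapse = "x")))
  invisible(x)
}
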