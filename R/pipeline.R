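#' Run the full analysis chain in memory
#'
#' Orchestrates the complete study on a synthetic cohort: generate volumes,
#' fit MTR/MTsat maps per scan, calibrate the MVF scaling constant on the
#' healthy-control arm, build g-ratio maps, summarise ROIs into the
#' long-format cohort table, and compute test-retest agreement (control arm)
#' and longitudinal statistics (patient arm).
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer RNG seed; the run is deterministic given the seed.
#' @param g_target control white-matter mean g-ratio used to calibrate the
#'   MVF scaling constant.
#' @param erode_iterations white-matter mask erosion depth (voxels).
#' @param covariates,interactions passed to \code{\link{longitudinal_table}}.
#' @return An object of class \code{mt_study}: list with \code{cohort_table},
#'   \code{agreement}, \code{longitudinal}, \code{calibration},
#'   \code{meta}, \code{config}, \code{seed}.
#' @export
run_study <- function(config = cohort_config(), seed = 1, g_target = 0.581,
                      erode_iterations = 1,
                      covariates = c("age", "sex", "lesion_load", "dmt"),
                      interactions = character()) {
  cohort <- generate_cohort(config, seed = seed)
  acq <- config$acq

  mt <- lapply(cohort$scans, function(tps) lapply(tps, function(sc)
    fit_mt_maps(sc$mt_on, sc$mt_off, sc$t1w, acq)))

  # calibrate k on first-session control white matter (eroded, no cerebellum)
  ctl <- cohort$meta$subject[cohort$meta$arm == "control"]
  tp1 <- names(cohort$scans[[ctl[1]]])[1]
  wm_masks <- lapply(ctl, function(sid) {
    m <- cohort$masks[[sid]]
    erode_mask(m$wm, erode_iterations) & !m$cereb
  })
  calib <- calibrate_k(
    mtsat = lapply(ctl, function(sid) mt[[sid]][[tp1]]$mtsat),
    icvf  = lapply(ctl, function(sid) cohort$scans[[sid]][[tp1]]$icvf),
    isovf = lapply(ctl, function(sid) cohort$scans[[sid]][[tp1]]$isovf),
    masks = wm_masks, g_target = g_target)

  maps <- lapply(names(cohort$scans), function(sid) {
    lapply(names(cohort$scans[[sid]]), function(tp) {
      sc <- cohort$scans[[sid]][[tp]]
      out <- list(mtsat = mt[[sid]][[tp]]$mtsat, mtr = mt[[sid]][[tp]]$mtr)
      if (!is.null(sc$icvf)) {
        gr <- fit_gratio_maps(out$mtsat, sc$icvf, sc$isovf, calib$k)
        out$icvf <- sc$icvf; out$isovf <- sc$isovf; out$g <- gr$g
      }
      out
    }) |> setNames(names(cohort$scans[[sid]]))
  }) |> setNames(names(cohort$scans))

  tab <- build_cohort_table(cohort, maps, erode_iterations)
  agr <- agreement_table(tab, arm = "control")
  lng <- longitudinal_table(tab, cohort$meta, arm = "patient",
                            covariates = covariates,
                            interactions = interactions)
  structure(list(cohort_table = tab, agreement = agr, longitudinal = lng,
                 calibration = calib, meta = cohort$meta, config = config,
                 seed = seed),
            class = "mt_study")
}

#' @exportS3Method base::print
print.mt_study <- function(x, ...) {
  cat(sprintf(
    "MT/g-ratio study (seed %s): %d subjects, k = %.4f, %d ROI rows\n",
    format(x$seed), nrow(x$meta), x$calibration$k, nrow(x$cohort_table)))
  invisible(x)
}

#' Significance/direction pattern of the longitudinal mixed models
#'
#' Reduces the mixed-model table of an \code{mt_study} to one label per
#' metric x region: "up" or "down" when the FDR-adjusted time effect is
#' significant, "ns" otherwise — the compact summary format used for
#' longitudinal cohort results.
#'
#' @param study an \code{mt_study} from \code{\link{run_study}}.
#' @param alpha significance level on the q-values.
#' @return Named character vector, names "region.metric".
#' @export
study_pattern <- function(study, alpha = 0.05) {
  lm <- study$longitudinal$lmm
  lab <- ifelse(lm$q < alpha, ifelse(lm$beta_time > 0, "up", "down"), "ns")
  setNames(lab, paste(lm$region, lm$metric, sep = "."))
}

#' Run the pipeline on disk with a provenance manifest
#'
#' File-based front end to \code{\link{run_study}}: optionally reads a YAML
#' configuration, simulates the cohort, writes every volume as NIfTI (1 mm
#' isotropic), writes the ROI table and statistics as CSV, and records a JSON
#' manifest listing inputs, outputs, parameters, seed and per-stage status.
#' Any stage failure aborts with a stage-tagged error and removes partial
#' tables.
#'
#' @param config a \code{\link{cohort_config}}, or the path to a YAML file
#'   whose keys are \code{cohort_config} arguments (nested tables are
#'   data.frame-coerced).
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @param write_volumes write per-scan NIfTI volumes (default TRUE; the
#'   tables alone are much faster).
#' @param ... passed to \code{\link{run_study}}.
#' @return Invisibly, the \code{mt_study}; side effect: files under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = 1,
                         write_volumes = TRUE, ...) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "gratiokit",
                   version = as.character(packageVersion("gratiokit")),
                   seed = seed, created = format(Sys.time(), tz = "UTC"),
                   stages = list(), outputs = character())

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- "ok"
    res
  }

  study <- stage("analysis", run_study(config, seed = seed, ...))

  if (write_volumes) {
    stage("write_volumes", {
      cohort <- generate_cohort(config, seed = seed)  # same seed, same data
      write_cohort_nifti(cohort, file.path(out_dir, "volumes"))
    })
    manifest$outputs <- c(manifest$outputs, "volumes/")
  }

  stage("write_tables", {
    wr <- function(df, f) {
      write.csv(df, file.path(out_dir, f), row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs, f)
    }
    wr(study$cohort_table, "cohort_table.csv")
    wr(study$meta, "metadata.csv")
    wr(study$agreement, "agreement.csv")
    wr(study$longitudinal$paired, "paired_tests.csv")
    wr(study$longitudinal$lmm, "lmm_results.csv")
    if (!is.null(study$longitudinal$correlations))
      wr(study$longitudinal$correlations, "correlations.csv")
    if (!is.null(study$longitudinal$subgroup))
      wr(study$longitudinal$subgroup, "subgroup_tests.csv")
    jsonlite::write_json(study$calibration,
                         file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c(manifest$outputs, "calibration.json")
  })

  manifest$parameters <- config_to_list(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(study)
}

#' Write a cohort's volumes and masks as NIfTI files
#'
#' One directory per subject/timepoint holding the echo images
#' (\code{mt_on_e1.nii.gz} ...), NODDI maps and uint8 masks, all with 1 mm
#' isotropic geometry.
#'
#' @param cohort an \code{mt_cohort}.
#' @param dir output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wv <- function(vol, path) {
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(1, 1, 1)), path)
    files <<- c(files, path)
  }
  for (sid in names(cohort$scans)) {
    for (tp in names(cohort$scans[[sid]])) {
      d <- file.path(dir, sid, tp)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      sc <- cohort$scans[[sid]][[tp]]
      for (con in c("mt_on", "mt_off", "t1w")) {
        for (e in seq_along(sc[[con]]))
          wv(sc[[con]][[e]], file.path(d, sprintf("%s_e%d.nii.gz", con, e)))
      }
      for (mp in c("icvf", "isovf"))
        if (!is.null(sc[[mp]])) wv(sc[[mp]], file.path(d, paste0(mp, ".nii.gz")))
      wml <- cohort$masks[[sid]]$wml[[tp]]
      wv(array(as.integer(wml), dim(wml)), file.path(d, "mask_wml.nii.gz"))
    }
    md <- file.path(dir, sid)
    for (mk in c("icv", "brain", "wm", "cereb")) {
      m <- cohort$masks[[sid]][[mk]]
      wv(array(as.integer(m), dim(m)),
         file.path(md, paste0("mask_", mk, ".nii.gz")))
    }
  }
  write.csv(cohort$meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(files)
}

#' Read a cohort configuration from YAML
#'
#' Top-level keys map to \code{\link{cohort_config}} arguments; the keys
#' \code{regions}, \code{effects} and \code{session_sd} may hold lists of
#' columns and are coerced to data.frames keyed by region.
#'
#' @param path YAML file.
#' @return A \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (tb in c("regions", "effects", "session_sd")) {
    if (!is.null(y[[tb]])) {
      df <- as.data.frame(y[[tb]], stringsAsFactors = FALSE)
      rownames(df) <- df$region
      y[[tb]] <- df
    }
  }
  if (!is.null(y$acq)) y$acq <- do.call(acq_params, y$acq)
  do.call(cohort_config, y)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$acq <- list(flip1 = config$acq$alpha1 * 180 / pi,
                  flip2 = config$acq$alpha2 * 180 / pi,
                  tr1_ms = config$acq$tr1 * 1000,
                  tr2_ms = config$acq$tr2 * 1000,
                  te_ms = config$acq$te * 1000)
  out
}
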