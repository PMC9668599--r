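# Small, fast cohort configurations used across test files.

tiny_config <- function(...) {
  cohort_config(n_patients = 4, n_controls = 3, n_dmri_missing = 0,
                grid = c(20, 20, 14), ...)
}

# configuration with every stochastic element switched off
noise_free_config <- function(...) {
  cfg <- tiny_config(voxel_noise_sd = 0, noddi_voxel_sd = 0, ...)
  cfg$session_sd[, c("mtsat", "icvf", "isovf", "r1")] <- 0
  cfg$regions[, grepl("_sd$", names(cfg$regions))] <- 0
  cfg
}

# default acquisition used in most numerical checks
ACQ <- acq_params()

# independent rational-model forward evaluation (kept separate from the
# package implementation on purpose)
oracle_rational <- function(A, r1, delta, flip, tr)
  A * flip * tr * r1 / (flip^2 / 2 + delta + tr * r1)
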