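test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- tiny_config()
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  expect_identical(a$scans, b$scans)
  expect_identical(a$masks, b$masks)
  c <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$scans, c$scans))
})

test_that("cohort structure honours the configuration", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg, seed = 1)
  expect_equal(sum(co$meta$arm == "patient"), 4)
  expect_equal(sum(co$meta$arm == "control"), 3)
  expect_named(co$scans[["P001"]], c("M0", "M12"))
  expect_named(co$scans[["C001"]], c("test", "retest"))
  expect_length(co$scans[["P001"]][["M0"]]$mt_on, 3)   # three echoes
  # controls carry no lesions and zero lesion load
  expect_true(all(co$meta$lesion_load_pct_icv[co$meta$arm == "control"] == 0))
  expect_false(any(co$masks[["C001"]]$wml[["test"]]))
  # masks nest: wm in brain in icv
  m <- co$masks[["P001"]]
  expect_true(all(m$icv[m$brain]))
  expect_true(all(m$brain[m$wm]))
  # NAWM survives erosion
  expect_gt(sum(erode_mask(m$wm & !m$wml[["M0"]])), 0)
})

test_that("degenerate grids are rejected", {
  expect_error(cohort_config(grid = c(6, 6, 4)), "grid")
})

test_that("zero noise and zero effects give exactly identical timepoints", {
  cfg <- noise_free_config()
  cfg$effects[, c("mtsat", "icvf", "isovf", "mtr")] <- 0
  co <- generate_cohort(cfg, seed = 3)
  sc <- co$scans[["P001"]]
  expect_identical(sc$M0$mt_on, sc$M12$mt_on)
  expect_identical(sc$M0$icvf, sc$M12$icvf)
  maps <- lapply(sc, function(s) fit_mt_maps(s$mt_on, s$mt_off, s$t1w,
                                             cfg$acq))
  expect_identical(maps$M0$mtsat, maps$M12$mtsat)
})

test_that("noise-free maps hit the generator's ground truth exactly", {
  cfg <- noise_free_config()
  co <- generate_cohort(cfg, seed = 4)
  sid <- "P001"
  truth <- co$truth[co$truth$subject == sid & co$truth$timepoint == "M0", ]
  sc <- co$scans[[sid]]$M0
  mt <- fit_mt_maps(sc$mt_on, sc$mt_off, sc$t1w, cfg$acq)
  m <- co$masks[[sid]]
  nawm <- erode_mask(m$wm & !m$wml$M0)
  tn <- truth[truth$region == "nawm", ]
  expect_equal(mean(mt$mtsat[nawm]), tn$mtsat, tolerance = 1e-9)
  expect_equal(mean(mt$mtr[nawm]), tn$mtr, tolerance = 1e-9)
  expect_equal(mean(mt$r1_app[nawm]), tn$r1, tolerance = 1e-9)
  expect_equal(mean(sc$icvf[nawm]), tn$icvf, tolerance = 1e-12)
  if (any(m$wml$M0)) {
    tw <- truth[truth$region == "wml", ]
    expect_equal(mean(mt$mtsat[m$wml$M0]), tw$mtsat, tolerance = 1e-9)
  }
})

test_that("prescribed annual effects shift the ground truth as configured", {
  cfg <- noise_free_config()
  co <- generate_cohort(cfg, seed = 5)
  tr <- co$truth[grepl("^P", co$truth$subject), ]
  w <- reshape(tr[, c("subject", "timepoint", "region", "mtsat", "icvf")],
               idvar = c("subject", "region"), timevar = "timepoint",
               direction = "wide")
  naw <- w[w$region == "nawm", ]
  expect_equal(naw$mtsat.M12 - naw$mtsat.M0, rep(-0.03, nrow(naw)),
               tolerance = 1e-12)
  expect_equal(naw$icvf.M12 - naw$icvf.M0, rep(0.002, nrow(naw)),
               tolerance = 1e-12)
  # MTR ground truth held still by the compensating R1 shift
  wm <- reshape(tr[, c("subject", "timepoint", "region", "mtr")],
                idvar = c("subject", "region"), timevar = "timepoint",
                direction = "wide")
  expect_equal(wm$mtr.M12, wm$mtr.M0, tolerance = 1e-9)
})

test_that("downstream pipeline recovers the planted study conditions", {
  st <- run_study(cohort_config(), seed = 11)
  row <- st$longitudinal$paired
  row <- row[row$metric == "mtsat" & row$region == "nawm", ]
  se <- row$sd_diff / sqrt(row$n)
  # NAWM MTsat annual change within 2 SE of the configured -0.03 percent
  expect_lt(abs(row$mean_diff - (-0.03)), 2 * se)
  # control white-matter MTsat near its configured 3.74 percent
  # (3 x the between-subject + session SE for n = 11)
  tab <- st$cohort_table
  ctl <- tab$arm == "control" & tab$timepoint == "test" &
    tab$metric == "mtsat"
  expect_lt(abs(mean(tab$mean[ctl]) - 3.74), 3 * 0.145 / sqrt(11))
  # calibrated control white-matter mean g at the target
  expect_equal(st$calibration$g_achieved, 0.581, tolerance = 1e-6)
})

test_that("control-arm test-retest bias is consistent with zero change", {
  cfg <- cohort_config(n_patients = 2, n_controls = 24, n_dmri_missing = 0,
                       grid = c(20, 20, 14))
  st <- run_study(cfg, seed = 12)
  agr <- st$agreement
  for (i in seq_len(nrow(agr))) {
    se <- agr$sd_diff[i] / sqrt(agr$n[i])
    expect_lt(abs(agr$mean_diff[i]), 4 * se)
    expect_gt(agr$sign_test_p[i], 0.001)
  }
})

test_that("rician noise keeps signals non-negative", {
  cfg <- tiny_config(noise_model = "rician", voxel_noise_sd = 0.3)
  co <- generate_cohort(cfg, seed = 6)
  expect_true(all(co$scans[["P001"]]$M0$mt_on[[1]] >= 0))
})

test_that("dMRI-missing subjects have no NODDI maps", {
  cfg <- cohort_config(n_patients = 6, n_controls = 2, n_dmri_missing = 2,
                       grid = c(20, 20, 14))
  co <- generate_cohort(cfg, seed = 7)
  miss <- co$meta$subject[co$meta$dmri_missing]
  expect_length(miss, 2)
  expect_null(co$scans[[miss[1]]]$M0$icvf)
  have <- setdiff(co$meta$subject[co$meta$arm == "patient"], miss)
  expect_false(is.null(co$scans[[have[1]]]$M0$icvf))
})
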