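test_that("echo summation is the voxelwise sum and validates grids", {
  e <- list(array(2, c(2, 2, 2)), array(3, c(2, 2, 2)), array(5, c(2, 2, 2)))
  expect_equal(sum_echoes(e), array(10, c(2, 2, 2)))
  expect_equal(sum_echoes(e[1]), e[[1]])          # single echo: identity
  expect_equal(sum_echoes(e[[1]]), e[[1]])        # bare array passthrough
  expect_error(sum_echoes(list(array(1, c(2, 2)), array(1, c(3, 2)))),
               "mismatched")
})

test_that("summing N iid-noise echoes raises SNR like sqrt(N)", {
  set.seed(11)
  n_draw <- 1e4
  snr <- sapply(c(1, 4), function(N) {
    sums <- colSums(matrix(1 + rnorm(N * n_draw, 0, 0.2), nrow = N))
    mean(sums) / sd(sums)
  })
  expect_equal(snr[2] / snr[1], 2, tolerance = 0.05)
})

test_that("MTR formula, invalid-voxel flagging and frozen example", {
  expect_equal(compute_mtr(0.5, 1.0), 50)
  expect_equal(compute_mtr(1.0, 1.0), 0)
  expect_true(is.nan(compute_mtr(0.5, 0)))       # background flagged, not 0
  s_off <- oracle_rational(1, 1, 0,     ACQ$alpha1, ACQ$tr1)
  s_on  <- oracle_rational(1, 1, 0.037, ACQ$alpha1, ACQ$tr1)
  expect_equal(compute_mtr(s_on, s_off), 52.2542, tolerance = 1e-4)
})

test_that("rational-model inversion recovers A, R1 and MTsat exactly", {
  set.seed(7)
  for (i in 1:25) {
    A <- runif(1, 0.3, 2); r1 <- runif(1, 0.4, 1.6); d <- runif(1, 0.005, 0.06)
    s_off <- simulate_flash_signal(A, r1, flip = ACQ$alpha1, tr = ACQ$tr1)
    s_t1w <- simulate_flash_signal(A, r1, flip = ACQ$alpha2, tr = ACQ$tr2)
    s_on  <- simulate_flash_signal(A, r1, d, ACQ$alpha1, ACQ$tr1,
                                   mt_on = TRUE)
    fit <- estimate_t1_amplitude(s_off, s_t1w, ACQ)
    expect_equal(fit$a_app, A, tolerance = 1e-12)
    expect_equal(fit$r1_app, r1, tolerance = 1e-12)
    expect_equal(compute_mtsat(s_on, fit$a_app, fit$r1_app, ACQ),
                 100 * d, tolerance = 1e-10)
  }
})

test_that("exact-SPGR forward signals give R1 recovery within 5 percent", {
  s_off <- simulate_flash_signal(1, 1, flip = ACQ$alpha1, tr = ACQ$tr1,
                                 model = "exact")
  s_t1w <- simulate_flash_signal(1, 1, flip = ACQ$alpha2, tr = ACQ$tr2,
                                 model = "exact")
  fit <- estimate_t1_amplitude(s_off, s_t1w, ACQ)
  expect_equal(fit$r1_app, 1, tolerance = 0.05)
})

test_that("exact-model MTsat bias shrinks as flip angles shrink", {
  bias_at <- function(flip1_deg, flip2_deg) {
    acq <- acq_params(flip1 = flip1_deg, flip2 = flip2_deg)
    d <- 0.037
    s_off <- simulate_flash_signal(1, 1, flip = acq$alpha1, tr = acq$tr1,
                                   model = "exact")
    s_t1w <- simulate_flash_signal(1, 1, flip = acq$alpha2, tr = acq$tr2,
                                   model = "exact")
    s_on <- simulate_flash_signal(1, 1, d, acq$alpha1, acq$tr1,
                                  model = "exact", mt_on = TRUE)
    fit <- estimate_t1_amplitude(s_off, s_t1w, acq)
    abs(compute_mtsat(s_on, fit$a_app, fit$r1_app, acq) - 100 * d)
  }
  b_small <- bias_at(3, 10)
  b_proto <- bias_at(5, 18)
  b_large <- bias_at(10, 30)
  expect_lt(b_small, b_proto)
  expect_lt(b_proto, b_large)
  expect_lt(b_proto, 0.2)     # bounded: below 0.2 MTsat percent at 5/18 deg
})

test_that("degenerate flip-angle pairs are flagged invalid", {
  # signals proportional so the R1 denominator vanishes or goes negative
  s_off <- 0.05
  s_t1w <- s_off * ACQ$alpha2 / ACQ$alpha1
  fit <- estimate_t1_amplitude(s_off, s_t1w, ACQ)
  expect_true(is.nan(fit$r1_app))
  expect_true(is.nan(fit$a_app))
  # and the flag propagates into MTsat
  expect_true(is.nan(compute_mtsat(0.03, fit$a_app, fit$r1_app, ACQ)))
})

test_that("no saturation means zero MTsat", {
  s_off <- simulate_flash_signal(1, 1, flip = ACQ$alpha1, tr = ACQ$tr1)
  s_t1w <- simulate_flash_signal(1, 1, flip = ACQ$alpha2, tr = ACQ$tr2)
  fit <- estimate_t1_amplitude(s_off, s_t1w, ACQ)
  expect_equal(compute_mtsat(s_off, fit$a_app, fit$r1_app, ACQ), 0,
               tolerance = 1e-12)
})

test_that("MTR and MTsat are invariant to global signal scaling", {
  A <- 0.8; r1 <- 1.1; d <- 0.03
  s <- c(off = simulate_flash_signal(A, r1, flip = ACQ$alpha1, tr = ACQ$tr1),
         t1w = simulate_flash_signal(A, r1, flip = ACQ$alpha2, tr = ACQ$tr2),
         on = simulate_flash_signal(A, r1, d, ACQ$alpha1, ACQ$tr1,
                                    mt_on = TRUE))
  for (c_scale in c(0.1, 3, 250)) {
    sc <- c_scale * s
    expect_equal(compute_mtr(sc["on"], sc["off"]),
                 compute_mtr(s["on"], s["off"]))
    f1 <- estimate_t1_amplitude(s["off"], s["t1w"], ACQ)
    f2 <- estimate_t1_amplitude(sc["off"], sc["t1w"], ACQ)
    expect_equal(compute_mtsat(sc["on"], f2$a_app, f2$r1_app, ACQ),
                 compute_mtsat(s["on"], f1$a_app, f1$r1_app, ACQ),
                 tolerance = 1e-10)
  }
})

test_that("MTsat is independent of T1 where MTR is not (two-tissue phantom)", {
  d <- 0.037
  tissue <- function(r1) {
    list(off = simulate_flash_signal(1, r1, flip = ACQ$alpha1, tr = ACQ$tr1),
         t1w = simulate_flash_signal(1, r1, flip = ACQ$alpha2, tr = ACQ$tr2),
         on = simulate_flash_signal(1, r1, d, ACQ$alpha1, ACQ$tr1,
                                    mt_on = TRUE))
  }
  t1 <- tissue(1.0); t2 <- tissue(0.6)   # same delta, different T1
  mtsat <- sapply(list(t1, t2), function(s) {
    f <- estimate_t1_amplitude(s$off, s$t1w, ACQ)
    compute_mtsat(s$on, f$a_app, f$r1_app, ACQ)
  })
  mtr <- sapply(list(t1, t2), function(s) compute_mtr(s$on, s$off))
  expect_equal(mtsat[1], mtsat[2], tolerance = 1e-10)
  expect_gt(abs(mtr[1] - mtr[2]), 1)     # MTR confounded by T1
})

test_that("fit_mt_maps runs the full chain on echo lists", {
  A <- array(0.7, c(4, 4, 4)); r1 <- array(0.9, c(4, 4, 4))
  d <- array(0.037, c(4, 4, 4))
  dec <- exp(-ACQ$te / 0.05)
  mk <- function(flip, tr, mt_on) lapply(dec, function(w)
    w * simulate_flash_signal(A, r1, d, flip, tr, mt_on = mt_on))
  maps <- fit_mt_maps(mk(ACQ$alpha1, ACQ$tr1, TRUE),
                      mk(ACQ$alpha1, ACQ$tr1, FALSE),
                      mk(ACQ$alpha2, ACQ$tr2, FALSE), ACQ)
  expect_s3_class(maps, "mt_maps")
  expect_equal(maps$mtsat[1, 1, 1], 3.7, tolerance = 1e-10)
  expect_equal(maps$r1_app[1, 1, 1], 0.9, tolerance = 1e-10)
})
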