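# gratiokit

Quantitative myelin-sensitive MRI for longitudinal white-matter studies, in
R. The package is aimed at neuroimaging researchers who work with
magnetisation-transfer and diffusion protocols in multiple sclerosis (and
similar white-matter conditions) and need a tested, reproducible path from
co-registered volumes to group-level statistics — plus a synthetic cohort
generator with known ground truth for validating every step when real
scanner data cannot be shared.

## What it computes

**MT parametric maps.** From a three-volume spoiled gradient-echo (FLASH)
protocol — a proton-density-weighted pair with and without an off-resonance
MT pulse (MT_on, MT_off; flip α₁ = 5°, TR₁ = 30 ms) and a T1-weighted
volume (α₂ = 18°, TR₂ = 15 ms), each with three summed echoes:

- MTR = 100 · (S_off − S_on) / S_off
- dual-flip-angle apparent amplitude and relaxation rate (A_app, R1_app),
  solved in closed form from the small-angle rational signal model
  S ≈ A α TR·R1 / (α²/2 + δ + TR·R1)
- MT saturation δ = (A_app·α₁/S_on − 1)·R1_app·TR₁ − α₁²/2, reported as
  percent. Unlike MTR, MTsat is analytically corrected for flip angle and
  T1.

**Aggregate g-ratio.** MVF = k·MTsat (k calibrated so healthy-control
white-matter mean g hits a target, default 0.581),
AVF = (1 − MVF)(1 − ISOVF)·ICVF from NODDI maps, and

    g = sqrt( AVF / (AVF + MVF) )

**ROI summaries and cohort statistics.** One-voxel 26-connectivity erosion
of normal-appearing white matter, mean/median/SD per region, brain
parenchymal fraction; Bland-Altman limits of agreement with exact sign
tests for control test-retest data; paired t-tests, covariate-adjusted
linear mixed models (ML, Satterthwaite df, BH-FDR within region, Nakagawa
marginal R²), change correlations and Welch subgroup tests for the
longitudinal patient arm; a sensitivity module sweeping g against its
inputs.

**Synthetic cohorts.** `generate_cohort()` simulates an RRMS-like
two-timepoint patient arm and a control test-retest arm: nested-ellipsoid
geometry with subject-specific lesions, three-echo FLASH signals forward
simulated from known (A, R1, δ), NODDI maps, masks, and subject metadata —
fully seeded and bit-reproducible.

## Worked example

```r
library(gratiokit)
acq <- acq_params()                       # 5/18 deg, TR 30/15 ms, 3 echoes

## forward-simulate one white-matter-like voxel (A = 1, R1 = 1/s, delta = 3.7%)
s_off <- simulate_flash_signal(1, 1, flip = acq$alpha1, tr = acq$tr1)
s_t1w <- simulate_flash_signal(1, 1, flip = acq$alpha2, tr = acq$tr2)
s_on  <- simulate_flash_signal(1, 1, delta = 0.037, flip = acq$alpha1,
                               tr = acq$tr1, mt_on = TRUE)
fit <- estimate_t1_amplitude(s_off, s_t1w, acq)
compute_mtsat(s_on, fit$a_app, fit$r1_app, acq)   # 3.7    (percent, exact)
compute_mtr(s_on, s_off)                          # 52.2542

## g-ratio of a typical white-matter voxel
mvf <- compute_mvf(3.7, k = 0.14)                 # 0.518
avf <- compute_avf(mvf, isovf = 0.075, icvf = 0.58)
compute_gratio(mvf, avf)                          # 0.57705

## a full synthetic study: 62 patients (M0/M12), 11 controls (test/retest)
st <- run_study(cohort_config(), seed = 42)
st$calibration$k                                  # 0.1392 (fraction per MTsat %)
st$agreement[1, c("mean_diff", "loa_low", "loa_high", "sign_test_p")]
#   mean_diff  loa_low loa_high sign_test_p      (control WM MTsat)
#   -0.004412 -0.15802  0.14919       0.549
subset(st$longitudinal$paired, region == "nawm" & metric == "mtsat")
#   n mean_diff     t       p                    (NAWM MTsat falls over 1 yr)
#  62   -0.0308 -3.11 0.00283
study_pattern(st)                                 # FDR-significant directions
# nawm.mtsat = "down", nawm.g = "up", wml.mtsat = "up", wml.icvf = "up", ...
```

The agreement table is the scan-rescan reference: its limits of agreement
(here ±0.15 % for control WM MTsat) bound the change expected in a healthy
subject, against which patient changes are judged. The paired table and the
mixed-model pattern show the longitudinal signal the generator planted:
NAWM MTsat falls by ≈ 0.03 %/yr while lesion MTsat, ICVF and ISOVF rise,
with MTR flat in both regions.

A thin command-line wrapper around the same functions ships in
`inst/cli/gratiokit` (subcommands `simulate`, `fit-mt`, `fit-gratio`,
`sensitivity`, `run`), reading and writing NIfTI volumes, CSV tables, YAML
configs and a JSON provenance manifest.

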