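---
title: "Models and methods behind gratiokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gratiokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gratiokit)
```

# What the package computes

gratiokit implements the quantitative-MRI measurement chain used to track
white-matter microstructure in longitudinal studies of recently diagnosed
relapsing-remitting multiple sclerosis (RRMS): myelin-sensitive parametric
maps (MTR and MTsat) from a three-volume spoiled gradient-echo (FLASH)
protocol, an aggregate MRI g-ratio combining MTsat with NODDI volume
fractions, eroded-ROI summaries, and the group statistics that turn per-scan
ROI values into test-retest reference limits and longitudinal effect
estimates. Because scanner data of this kind are access-restricted, the
package ships a forward simulator that generates co-registered
multi-contrast cohorts with known ground truth, so every estimator in the
chain can be validated end to end.

# Signal model and MT saturation estimation

The spoiled gradient-echo steady state for excitation flip angle
$\alpha$ and repetition time $TR$ is

$$S = A \sin\alpha \frac{1 - e^{-TR \cdot R_1}}{1 - \cos\alpha \, e^{-TR \cdot R_1}},$$

with amplitude $A$ (proton density and receiver gain) and apparent
longitudinal rate $R_1$. An off-resonance MT pulse played each TR saturates
a fraction $\delta$ of the longitudinal magnetisation; it enters the steady
state as an extra factor $(1-\delta)$ on the recovered magnetisation. In
the small-angle, short-TR regime this is well approximated by the rational
form

$$S \approx \frac{A\,\alpha\, TR \cdot R_1}{\alpha^2/2 + \delta + TR \cdot R_1},$$

which is the model the estimators invert. From the non-saturated pair
(low-flip MT\_off, high-flip T1-weighted volume) the closed-form
dual-flip-angle solutions give apparent $R_1$ and $A$ maps; MTsat then
follows voxelwise as

$$\delta = \left(\frac{A^{app}\alpha_1}{S_{on}} - 1\right) R_1^{app}\, TR_1 - \frac{\alpha_1^2}{2},$$

reported as percent. The $\alpha_1^2/2$ term and the explicit
$R_1^{app}$ dependence are what make MTsat robust to T1: two tissues with
equal $\delta$ but different $R_1$ return equal MTsat while their MTR —
$100\,(S_{off} - S_{on})/S_{off}$ — differs. This inversion is *exact* for
rational-model signals (the test suite checks recovery to machine
precision over randomised tissue parameters) and biased by a bounded,
small-flip-angle-controlled amount for exact-SPGR signals (about 1 % on
$R_1$ and 2–3 % on $\delta$ at the default 5°/18°, TR 30/15 ms protocol).
Echoes are magnitude-summed before any ratio is formed, which raises ROI
SNR by roughly $\sqrt{N}$; whether the original acquisition summed
magnitudes or complex data is not recorded, and magnitude summation is
assumed.

No B1 correction is applied: the emulated protocol acquired no B1 map, and
MTsat's first-order robustness to transmit-field error is relied upon. This
is a documented limitation, not a modelling claim.

# Aggregate g-ratio

The myelin volume fraction is taken as linearly scaled MTsat,
$MVF = k \cdot MTsat$, and the axonal volume fraction combines the NODDI
fractions with the myelin complement,
$AVF = (1 - MVF)(1 - ISOVF)\,ICVF$. The aggregate g-ratio is

$$g = \sqrt{\frac{AVF}{AVF + MVF}} = \sqrt{\frac{1}{1 + MVF/AVF}},$$

which satisfies the boundary identities $g = 1$ for unmyelinated tissue
($MVF = 0$) and $g = \sqrt{1/2}$ at $MVF = AVF$, and depends on the two
fractions only through their ratio. The square-root form is used
deliberately: the linear form printed in some reports (a typesetting loss
of the radical) fails both identities and cannot reproduce healthy
white-matter values near 0.58.

The scaling constant $k$ is not portable across sites and sequences, so it
is calibrated: `calibrate_k()` finds the $k$ at which the pooled mean g over
healthy-control white-matter voxels equals a target (default 0.581, a
typical healthy-control value for this calibration style), by monotone 1-D
root finding to $10^{-6}$. Slope-only scaling is assumed (no intercept), as
the exact linear map used in any given study is rarely printed. Voxels
driven to $AVF \le 0$ are undefined and flagged `NaN` (inside the
calibration objective only, the fully myelinated limit counts as $g = 0$ to
keep the objective monotone). The cerebellum is excluded from all
diffusion-derived metrics via an exclusion mask, mirroring common practice
when dMRI coverage or distortion is unreliable there.

The sensitivity module (`sweep_g()`) makes the competing dependencies
explicit by sweeping one input over a biologically realistic range with the
others fixed: g falls as MTsat rises, rises with ICVF, and falls with
ISOVF. Default ranges (MTsat 1.7–4.3 %, ICVF 0.27–0.65, ISOVF 0.04–0.19)
span the values observed across healthy white matter, normal-appearing
white matter and lesions in a recently diagnosed RRMS cohort.

# Regions of interest and summaries

Normal-appearing white matter (NAWM) is the supplied white-matter mask
minus the lesion mask, eroded by one voxel with a 3×3×3 box
(26-connectivity) structuring element — the kernel most neuroimaging tools
default to; the erosion limits partial-volume contamination at tissue
borders. Volume edges are treated as background, so masks also erode at the
field-of-view boundary. ROI summaries (mean, median, SD, voxel count)
exclude voxels flagged invalid by the mapping stage rather than clamping
them, so noise-floor and background voxels cannot bias group statistics.
The subject-level statistic carried into group tests is the ROI **mean**
(the tables this layout mirrors report means with ranges). The brain
parenchymal fraction is the voxel-count ratio of brain tissue (including
lesions) to intracranial volume.

# Group statistics

*Test-retest agreement* (control arm): Bland-Altman mean difference and
95 % limits of agreement $\bar d \pm 1.96\,s_d$ (fixed 1.96 multiplier, the
standard convention), plus an exact two-sided binomial sign test — at
$n \approx 9$–11 pairs the normal approximation is inaccurate, and the
exact form reproduces published p-values such as 0.549 for a 7/11 split.
Zero differences are dropped and logged.

*Longitudinal inference* (patient arm): paired t-tests per metric and
region, followed by linear mixed models
`value ~ time + age + sex + lesion_load + dmt + (1 | subject)` fitted by
maximum likelihood (not REML), with Satterthwaite degrees of freedom via
lmerTest. Benjamini–Hochberg FDR correction is applied across the
per-metric time-effect p-values *within each region* — the narrowest
family consistent with how such analyses are reported. Nakagawa's marginal
$R^2 = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$ is computed
directly from the variance components ($\sigma^2_f$ is the variance of the
fixed-effect predictions). Interaction terms with time are config-driven
and default to none, since which interactions were "appropriate" in the
original analyses is not enumerated; covariates constant in a given sample
(for example a single-sex subgroup) are dropped automatically rather than
producing rank-deficient fits. Changes between metrics are related by
Pearson correlations, and new-lesion subgroups compared with Welch t-tests.
Estimated marginal means are out of scope; the raw time coefficient is
reported instead.

# What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws, per subject and region (healthy-control white
matter; patient NAWM; lesions), the parameters the estimators target:
MTsat (percent), ICVF, ISOVF, and an MTR target from which the apparent
$R_1$ is solved under the rational model. Defaults reproduce the
cross-sectional means of a recently diagnosed RRMS cohort and its
healthy-control arm (e.g. control WM MTsat 3.74 %, ICVF 0.605, ISOVF
0.086, MTR 54.5 %; NAWM MTsat 3.80 %; lesion MTsat 2.35 %, ICVF 0.379).
The implied baseline $R_1$ values — 0.91/s in control WM, 0.94/s in NAWM,
0.75/s in lesions — correspond to T1 around 1.1 s in white matter and
1.3 s in lesions, which is physiologically sensible; they are derived, not
independently printed values.

Three noise tiers are simulated:

* **between-subject** SDs (control SDs from the reported cross-sectional
  values; patient SDs set to a quarter of the reported ranges);
* **session (scan-rescan)** perturbations of each ROI parameter, with SDs
  equal to the reported test-retest difference SDs divided by $\sqrt 2$,
  so that control Bland-Altman difference SDs land on the reported scale
  (the $R_1$ session SD is chosen so the implied MTR difference SD does
  too); and
* **voxel noise**, additive Gaussian by default (SNR ≈ 50 on the echo
  images, high enough that ROI means are dominated by the session tier —
  only ROI-level difference SDs are reported in the literature, so voxel
  noise is otherwise unconstrained), with an optional Rician mode.

Patient follow-up applies fixed annual effects (defaults: NAWM MTsat
−0.03 %, ICVF +0.002; lesion MTsat +0.08 %, ICVF +0.021, ISOVF +0.010).
MTR follows its own prescribed trajectory — zero change by default — by
co-adjusting $R_1$ with the MTsat shift. This encodes the standard
interpretation that T1 prolongation accompanies demyelination and largely
cancels MTR's sensitivity to it; it is also the only way a generator
without confounder structure can reproduce an "MTR null" mixed-model
outcome alongside a real MTsat change. Treatment initiation is assigned to
exactly `round(38/62 * n)` patients so the demographic fraction is
reproducible rather than binomially noisy.

Geometry is deliberately schematic: nested ellipsoids (intracranial volume,
brain, white-matter slab) on a 32×32×16 grid of 1 mm isotropic voxels,
with spherical lesions placed inside the white matter to match each
patient's lesion load (capped at a quarter of the white-matter volume so an
eroded NAWM always remains) and an inferior slab standing in for the
cerebellum exclusion. Volumes are born co-registered; there is no
registration error, no k-space or coil simulation, no field inhomogeneity,
no partial-volume mixing at tissue borders, and NODDI maps are generated
directly as parameter fields rather than from diffusion signals. Passing
tests therefore demonstrate estimator and statistics correctness under the
stated noise model — not robustness to registration, segmentation or
model-fit failures in real data.

The grid size, 20-replicate replication checks and 10^4-draw Monte-Carlo
oracles used in the test suite were chosen to keep a full run at desk
scale (a few minutes) while leaving Monte-Carlo error well inside the
asserted tolerances.

# Numerical and design choices

* MTsat is stored as a fraction internally and reported ×100, matching the
  percent scale (≈ 3.7 in white matter) used in the literature.
* Invalid voxels (non-positive denominators, background, $AVF \le 0$) are
  flagged `NaN` and excluded from ROI statistics — never clamped, which
  would bias means. Negative MTsat from noise is retained.
* Two forward models are kept side by side: `rational` (identical to the
  estimator's model, enabling exact-recovery tests that isolate estimator
  bugs from model error) and `exact` (Ernst steady state, used to bound the
  approximation bias).
* MVF clipping to [0, 1] is counted and warned about rather than silent.
* Calibration brackets $k$ in $[10^{-4}, 1]$ fraction per MTsat-percent and
  fails loudly if the target mean g is unattainable there.
* Lesion masks are fixed between timepoints by default (manual lesion-mask
  editing is not reproducible); an option grows one new lesion per selected
  patient to exercise the new-lesion subgroup comparison.

# Known limitations

MTsat here carries no explicit B1 correction; the g-ratio model ignores
fibre orientation dispersion at the sub-voxel level and is unreliable where
ISOVF is large (severely damaged lesions); the simulator's uniform-tissue
geometry cannot expose partial-volume or registration failure modes; and
with the reported effect sizes and test-retest noise for NAWM MTsat
(a mean annual change of 0.03 % against a difference SD near 0.1 %), a
62-patient study has only moderate power, so replicate cohorts will not
reproduce the full significance pattern much more often than about half
the time — an inherent property of those study conditions, which the
replication checks in this package measure rather than hide.
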