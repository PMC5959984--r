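---
title: "Isotoxic dose prescription for SRS of brain metastases: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotoxic dose prescription for SRS of brain metastases: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpsrs)
```

## The prescription problem

Single-fraction SRS doses for brain metastases are set by PTV size: 24 Gy
below 1 cm³, then 21, 18 and 15 Gy for PTVs in [1, 10), [10, 20) and
[20, 65] cm³. We use half-open bins with a closed top edge; the literature
states the interior edges ambiguously ("between 1–10"), and this
convention is the one under which the three documented prescription
transitions caused by margin growth — 24→21 Gy at 1.0 cm GTV, 21→18 Gy at
2.5 cm and 18→15 Gy at 3.0 cm, all with a 2 mm margin — are reproduced
exactly. The 65 cm³ top edge doubles as the SRS eligibility limit:
`prescribe_by_ptv_size()` refuses larger volumes rather than
extrapolating.

Fixed-dose prescription ignores the normal-tissue constraint that
actually limits safety: the volume of healthy brain minus GTV receiving
12 Gy or more in a single fraction should stay below 10 cm³, above which
the radionecrosis risk rises steeply. Isotoxic dose prescription (IDP)
instead scales each plan (equivalent to altering monitor units) until the
constraint is met exactly, making the tumor dose — and the predicted
TCP — the best achievable at a fixed, low toxicity risk.

## The radial plan surrogate

No voxel dose distributions are available for the benchmark plans; what is
available is each plan's RTOG conformity index (CI) and Paddick gradient
index (GI). These two numbers determine exactly a two-parameter radially
symmetric surrogate:

$$D(r) = D_{rx}\left(\frac{r_{rx}}{r}\right)^{k},\quad r \ge r_{rx};
\qquad r_{rx} = \Big(\frac{3\,CI\,V_{PTV}}{4\pi}\Big)^{1/3},\quad
k = \frac{3\ln 2}{\ln GI}.$$

The prescription isodose sphere has the volume the CI dictates, and the
half-prescription isodose has GI times that volume, so recomputing CI and
GI from the calibrated model returns the inputs identically — the
round-trip is part of the test suite. Inside the prescription isodose the
dose ramps linearly from the tabulated maximum at the centre down to
$D_{rx}$ at the surface; this inner ramp never affects healthy-brain DVHs
and exists only so grid-level maximum-dose checks are possible. The
tabulated mean PTV dose is deliberately not enforced: a two-parameter
radial profile cannot match four indices, and CI/GI are the two that
control healthy-brain dose.

Assumptions worth stating plainly:

* **Radial symmetry.** Real VMAT dose distributions are anisotropic;
  the surrogate attributes all falloff behaviour to one exponent. The two
  published healthy-brain V₁₂Gy values for the 4 cm target (13 and 33 cm³)
  are reproduced at 12.07 and 30.69 cm³, i.e. within about 7% — the
  residual is the price of radial symmetry.
* **Infinite homogeneous medium.** No skull or air boundary truncates the
  dose; benchmark targets were placed deep in the parietal lobe, so the
  approximation is mild for the volumes that matter (≤ tens of cm³).
* **Monotone falloff.** $V(\text{level})$ is strictly decreasing in dose
  level and increasing in GTV size, margin and GI when one input varies at
  a time. Note that along the *benchmark table* the margin trend can
  invert locally because CI and GI change between rows (e.g. the 0.5 cm
  coplanar plans, where CI drops from 2.5 to 1.2 between 1 and 2 mm
  margins); the tests therefore assert strict monotonicity at model level
  and only the average tendency at sweep level.

## Isotoxic renormalisation

Because renormalisation is a global scaling, the constraint isodose of the
renormalised plan must enclose the volume $V_c + V_{GTV}$, giving the
closed form

$$D_{IDP} = D_c \left(\frac{r_c}{r_{rx}}\right)^{k}, \qquad
r_c = \Big(\frac{3\,(V_c + V_{GTV})}{4\pi}\Big)^{1/3}.$$

`idp_dose_analytic()` asserts after every call that the achieved volume at
the constraint level equals the constraint volume (relative tolerance
1e-6). One degenerate regime exists: for the largest target with the
largest margin the PTV itself exceeds $V_c + V_{GTV}$, the constraint
isodose falls inside the PTV, and the inner ramp rather than the power law
governs. The result is then flagged `constraint_inside_ptv`, the isotoxic
dose drops below the constraint level, and exactness is not asserted.

The DVH route (`renormalize_dvh_to_constraint()`) is the independent path
used to validate the closed form: render the model on a grid, accumulate
the healthy-brain DVH, and scale so `d_at_volume(V_c)` lands on the
constraint level. Both paths agree within 2% at 1 mm grid spacing across
all 48 configurations.

## Fractionation and TCP

Constraints move between fractionation schemes through the
linear-quadratic model at α/β = 3 Gy for late brain toxicity:
the single-fraction 12 Gy level has BED 60 Gy, whose three-fraction
isoeffective total dose is 19.17 Gy. The clinical constraint set
(`srs_constraints()`) uses the rounded 19.2 Gy actually quoted for
three-fraction practice, alongside the independently established
five-fraction V₂₀Gy = 20 cm³; `convert_constraint()` keeps the exact
conversion for callers who want it.

TCP is logistic in the tumor BED at α/β = 12 Gy, the convention for
brain-metastasis dose–response data. The published model behind the
reference TCP figures is not available in parametric form, so the default
is a two-anchor calibration: 42% at 1 × 15 Gy (BED₁₂ 33.75 Gy) and 86% at
1 × 24 Gy (BED₁₂ 72 Gy), giving β₁ = 0.0559 per Gy and β₀ = −2.209.
Where two reported figures conflicted (42% vs "around 40%"), the value
stated twice and to higher precision was used. Consequences: the anchors
are reproduced exactly, orderings (TCP rising with dose, falling with
fraction number at fixed total dose, fractionated IDP dominating
single-fraction IDP for GTV ≥ 2.5 cm) are reproduced, but intermediate
published percentages from the unpublished fit (e.g. 32% at 14 Gy — this
calibration gives 37%) are not numeric targets. The model is pluggable:
any `tcp_model(beta0, beta1, alpha_beta_tumor)` can be passed to the
sweep.

## The synthetic cohort

The validation cohort of 46 delivered clinical plans (non-spherical GTVs,
2 mm margin, coplanar VMAT, 15–24 Gy in 1–3 fractions) is not available;
`generate_cohort()` emulates it. Within this framework a plan influences
the isotoxic dose only through (V_PTV, CI, GI), so non-sphericity and
planner variability are injected where they act: the GI interpolated from
the coplanar 2 mm benchmark rows (linear in log volume) is perturbed
multiplicatively by exp(N(0, σ)), truncated below at 1.05. PTV volumes are
drawn log-uniformly over 0.5–65 cm³ — no clinical volume histogram is
published, and a log-uniform spread covers all prescription bins without
concentrating mass at either extreme. All multi-fraction comparisons treat
the cohort as single-fraction-equivalent, since how the mixed-fraction
clinical plans entered the single-fraction comparison is not documented.

The noise scale σ is the one tunable without a stated value. It is
calibrated by `tune_noise()` — monotone bisection of the Monte-Carlo mean
per-cohort SD of (spherical-curve minus cohort) single-fraction isotoxic
doses — against the published scatter of 1.70 Gy, giving the frozen
default σ = 0.172. The test suite verifies on held-out seeds that the
mean per-cohort SD lands within 10% of 1.70 Gy; an individual 46-patient
cohort's SD is far more variable, which is why the criterion is a
Monte-Carlo mean. What passing these tests shows is that the emulation
reproduces the published *scatter magnitude and fit compatibility*; it
does not show the generator reproduces real anatomical shape
distributions, clinical volume mix, or planner-specific systematics.

The spherical-vs-cohort comparison fits $D(V) = d_\infty + d_0
e^{-V/v_0}$ to both arms (`fit_exp_decay()`, Levenberg–Marquardt with
three fixed decay-scale starts of 2, 10 and 30 cm³, best residual kept)
and reports two statistics (`compare_fits()`): the Pearson chi-squared of
cohort doses against the spherical curve on n − 3 degrees of freedom, and
a seed-controlled bootstrap Wald test on the coefficient difference
(default 2000 resamples; covariance inverted by Moore–Penrose
pseudo-inverse since exponential coefficients can be nearly collinear).
The bootstrap is included because a Pearson statistic on continuous doses
is a heuristic; it is also the test with real power against a uniform dose
shift, as the power test in the suite shows. One figure-caption-level
ambiguity in the source material (logistic regression vs exponential
decay for the fitted curve) was resolved in favour of exponential decay,
which is the form the fitting text describes.

## Numerical conventions

* **Voxelisation.** Grids sample dose at voxel centres, masks are
  centre-in-sphere, volumes are voxel count × voxel volume, default
  spacing 1 mm (the clinical calculation grid). The lattice is offset a
  quarter voxel from the target centre: with centre- or corner-aligned
  lattices, entire voxel planes cross an isodose sphere simultaneously and
  V₁₂Gy errors reach several percent at 1 mm, while the quarter offset
  keeps the worst configuration below 1% — and a treatment-planning grid
  is in any case not aligned to the lesion. Grid-vs-analytic agreement
  tightens monotonically over 2 → 1 → 0.5 mm in the test suite.
* **DVHs.** Cumulative, 0.1 Gy default bin width, linear interpolation for
  $V_x$/$D_x$ queries; `d_at_volume()` breaks ties on flat segments toward
  the higher dose so that renormalisation errs on the conservative side;
  rescaling multiplies the dose axis (query-exact, no re-binning).
* **Index round-trips.** CI/GI from the analytic model are exact. From
  grids they are verified within 1% using spacing ≤ 0.5 mm, refined to
  0.25 mm for the 0.5 cm targets whose PTV radius would otherwise span
  only five voxels.
* **Grid extent.** Defaults to covering the 1 Gy isodose (capped at
  10 cm); a grid whose boundary dose still exceeds 1 Gy is flagged
  truncated with a warning rather than silently under-counting.

## Problem sizes

The factorial sweep is 48 closed-form configurations and runs in well
under a second. Grid-based validation uses 1 mm voxels over extents
covering the 12 Gy isodose (up to ~70³–130³ voxels per configuration).
Cohort Monte-Carlo checks use 46-patient cohorts over 100–120 seeds for
the scatter calibration and 40 seeds for the fit-compatibility rate;
bootstrap tests in the suite use 150–200 resamples, while the exported
default is 2000.

## Limitations

* The surrogate inherits only CI and GI from a plan; Dmean and any
  anisotropy are not represented, which is the likely source of the ~7%
  understatement of the two published V₁₂Gy reference values.
* The TCP model has prescription dose as its only covariate — no tumor
  volume, histology or hypoxia effects — and its two-anchor calibration is
  exact by construction rather than fitted to patient-level data.
* Only the healthy-brain constraint is modelled; brainstem and optic
  pathway constraints, multi-metastasis plans, and re-optimisation (as
  opposed to pure renormalisation) are out of scope.
* The eligibility ceiling (65 cm³) and the constraint set apply to 1, 3
  and 5 fractions only; no dose–volume thresholds exist in the modelled
  framework for other schemes.
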