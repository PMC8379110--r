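---
title: "Quantifying periablational safety margins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periablational safety margins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ablmargin)
```

## The problem

Thermal ablation of a liver metastasis is judged successful not merely when
the necrosis zone covers the tumor, but when it also covers a *periablational
safety margin* — a shell of liver tissue extending a fixed distance beyond
the tumor boundary, intended to destroy microscopic satellite disease.
Local tumor progression (LTP), the reappearance of tumor at the ablation
site, is strongly tied to how much of that shell was left unablated.

`ablmargin` quantifies this volumetrically. Given two co-registered binary
segmentations on one voxel grid — tumor and ablation zone — it computes, for
every margin width $m$ (by default 1–10 mm):

* the **unablated safety-margin percentage**
  $$U_m = 100 \cdot
    \frac{\mathrm{vol}(\mathrm{shell}_m \setminus \mathrm{ablation})}
         {\mathrm{vol}(\mathrm{shell}_m)},$$
  where $\mathrm{shell}_m$ is the set of voxels within $m$ mm of the tumor
  but not in it;
* the **residual tumor percentage**
  $R = 100 \cdot \mathrm{vol}(\mathrm{tumor} \setminus
  \mathrm{ablation}) / \mathrm{vol}(\mathrm{tumor})$;
* a **five-class completeness grade** per margin: residual tumor present
  (`INCOMPLETE`, $R$ above tolerance); otherwise `SM100` ($U_m = 0$,
  margin fully ablated), `SM95_100` ($0 < U_m < 5$), `SM90_95`
  ($5 \le U_m \le 10$), `SM_LT90` ($U_m > 10$).

Cohort-level tools then reproduce the statistics such a study reports:
per-margin completeness-by-LTP tables, chi-square/Fisher association tests,
Kaplan–Meier LTP-free survival with log-rank comparisons, ROC analysis, the
100%-sensitivity threshold on $U_m$, and green/gray/red zone bands.

## Geometry

**Distance semantics.** All shell geometry derives from one exact Euclidean
distance transform of the tumor mask, computed with the separable
lower-envelope algorithm in compiled code. Distances are measured between
*voxel centers* in physical millimetres, honouring anisotropic spacing
(follow-up CT in this setting typically has ~1-mm in-plane resolution and
3-mm slices, the package default for phantoms). Volumetric voxel dilation —
rather than a surface-mesh distance — was chosen because it is exactly
reproducible and admits a brute-force all-pairs oracle; the test suite
asserts bit-exact agreement with that oracle on small grids.

**Shell membership** is $0 < d \le m$, closed at $m$: a voxel center exactly
3 mm from the tumor belongs to the 3-mm margin. Thresholding is done on
squared distances with a $10^{-9}$ relative tolerance — large enough to
absorb floating-point error in $\sum_k s_k^2\,\Delta_k^2$, far smaller than
any between-voxel distance gap.

**Counting is whole-voxel.** A voxel is in or out by its label; there is no
partial-volume weighting. On sphere phantoms the resulting $U_m$ converges
to the closed-form shell fraction
$100\,\big((r_t+m)^3 - r_a^3\big)/\big((r_t+m)^3 - r_t^3\big)$ as voxels
shrink; the suite asserts monotone error decrease over 2, 1 and 0.5-mm
voxels. One consequence worth knowing: discrete dilation is biased slightly
*inward* (about half a voxel at the surface), so the dilated volume of a
voxelized sphere undershoots the analytic ball by ~4% at 1-mm voxels,
falling under 2% at 0.5 mm. Ratios of volumes ($U_m$, $R$) are much less
affected because the bias largely cancels.

**Clipping is an error.** If an expansion would reach the array face, the
computation stops with an explicit error instead of silently truncating the
shell — truncation biases $U_m$ downward, the unsafe direction. Callers pad
their volumes instead.

**Residual tolerance.** By default any uncovered tumor voxel marks the case
`INCOMPLETE`. `assess_case(residual_tol_mm3 =)` accepts an absolute volume
below which sub-voxel leftovers (segmentation noise at 3-mm slices can
amount to a voxel or two) are ignored; the threshold is deliberately a
volume, not a percentage, because noise scales with voxel size rather than
tumor size.

## Thresholds and bands

The **100%-sensitivity cut-off** at a margin is the largest value on a
0.1-point grid lying *strictly below* every LTP case's $U_m$: any tumor at
or below it would have been progression-free in the data. The one-decimal
grid matches the precision at which such percentages are reported; the
"largest grid value below the LTP minimum" convention is an interpretation
(the original analysis software's exact ROC convention is not published) and
is stated here so results are unambiguous. The ROC AUC uses the
Mann–Whitney pairwise-concordance form with ties counting one half, which
equals the trapezoidal area under the sensitivity/specificity sweep.

**Zone bands** partition the $U_m$ axis at one margin: *green* below the
100%-sensitivity cut-off (only seen without LTP), *red* above the largest
non-LTP value (only seen with LTP), *gray* in between (both outcomes
observed). The gray band is empty exactly when the outcome groups separate.

## Statistical conventions

* Unit of analysis is the tumor, not the patient; no clustering adjustment
  is applied (several tumors may share a patient). This mirrors the study
  design the package emulates and is a known limitation.
* Chi-square tests are uncorrected by default (`correct = FALSE`); for 2×2
  tables with any expected count below 5, the two-sided Fisher exact test
  is used instead. The Yates correction is available by flag.
* Cases without LTP are right-censored at last follow-up; Kaplan–Meier and
  log-rank computations are delegated to the `survival` package and
  verified in the suite against hand product-limit and
  observed-minus-expected arithmetic.
* Raw univariate p-values are reported; no multiplicity adjustment.

## The embedded reference cohort

`ltp_reference_cohort()` ships the nine progressing tumors of the
published stereotactic-RFA cohort this package models — per-tumor $U_m$ for
1–10 mm, residual percentage, time to LTP, and covariate flags, transcribed
at printed precision. `verify_reference()` recomputes 56 aggregates from
those nine rows alone (per-margin class tallies, the 3-mm/"no fully covered
LTP" and 6-mm/"no LTP above 90% coverage" rules, the 3.2%/11.2%
100%-sensitivity cut-offs, the 18.3 ± 11.9-month time-to-LTP summary) and
compares each to its embedded expected value:

```{r}
v <- verify_reference()
all(v$pass)
tail(v, 6)[, c("check", "expected", "computed")]
```

One transcription note: the source prints one ambiguous cell run for case
77; the reading used (time 7.5 months, residual 69.1%) reproduces the
published time-to-LTP summary and affects no margin-profile quantity.
Cohort-level class denominators (e.g. 55 tumors fully covered at 3 mm)
involve the 67 non-progressing tumors whose profiles were never published;
they are shipped as printed constants in `reference_class_totals()` and are
*not* recomputable. For the same reason the published survival rates, AUCs,
specificities and the 19.3% upper gray bound cannot be reproduced from
shipped data; the suite substitutes oracle-based property tests for those
estimators.

## Synthetic data

Two generators make every stage testable without clinical data.

**Sphere phantoms** (`make_sphere_phantom`) voxelize two analytic spheres
by center inclusion — tumor centered, ablation displaced by an arbitrary
offset so that all partial-coverage classes are reachable — and come with
the closed-form oracle `analytic_margin_fraction()` built from
sphere–sphere lens volumes. Default spacing is 1 × 1 × 3 mm; the in-plane
value is a convention (only the slice thickness of the emulated protocol is
known), and isotropic spacings are used wherever a test needs finer
convergence.

**The cohort simulator** (`simulate_cohort`) works directly in percentage
space — statistics tests need hundreds of cases, geometry tests need few —
under a radial coverage-deficit model: each case has a deficit depth $D$
(log-normal, median 4 mm) over a solid-angle fraction $f$ (Beta(2, 6),
mean 0.25), giving
$U_m = 100 f \,\big((r_t+m)^3 - (r_t+D)^3\big)/\big((r_t+m)^3 - r_t^3\big)$
for $m > D$ and 0 otherwise — non-decreasing in $m$ by construction, the
same nesting the clinical profiles show. LTP follows a threshold rule
($U_{m^\*} > \tau$, defaults $m^\* = 6$, $\tau = 10$ — the boundary of the
≥90%-coverage classes) flipped with probability $\varepsilon = 0.05$. Times
to LTP are log-normal with meanlog 2.7305 and sdlog 0.5939, matching the
18.3 ± 11.9-month moments of the reference times (positive and
right-skewed); censoring is uniform over 12–60 months of administrative
follow-up. Tumor sizes (log-normal around 20 mm, clamped to 3–75 mm) and
covariate prevalences mirror the emulated cohort's descriptive statistics.
All randomness sits behind one seed, recorded in the output, and identical
seeds reproduce cohorts and phantom masks bit-for-bit.

These defaults are the package's own choices, not estimates of any real
cohort: the simulator emulates the *structure* of the data (nested
profiles, a threshold-driven outcome, right-censoring), not CT intensities,
vessel-cooling artifacts, irregular tumor shapes, or registration error.
Passing tests therefore demonstrate correctness of the computations, not
clinical performance on real images.

## Problem sizes and numerical choices

The suite verifies geometry on grids up to $24^3$ against the brute-force
oracle, convergence on sphere phantoms down to 0.5-mm voxels (grids around
$85^3$), Fisher enumeration exhaustively to $N = 12$ plus 400 random tables
to $N = 40$, a $10^5$-draw permutation oracle for the chi-square, a
2000-replicate type-I-error simulation for the pooled t test, and threshold
recovery on noiseless simulated cohorts of 500 cases — sizes at which every
oracle is exact or its Monte-Carlo error is far below the asserted
tolerance, while the whole suite stays fast enough to run on every change.

## Known limitations

* Registration quality is assumed, asserted only as shape/spacing equality;
  resampling and non-rigid alignment are out of scope.
* Voxel-center distances on 3-mm slices quantize margins coarsely along the
  slice axis; sub-voxel margins (below the in-plane spacing) yield empty
  shells and an explicit error rather than a meaningless percentage.
* No patient-level clustering, no multivariable modelling, no AUC
  confidence intervals — matching the univariate design the package
  reproduces.
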