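---
title: "Methods: extracellular flux analysis of sperm energy metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracellular flux analysis of sperm energy metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcap)
```

## The measurement and its structure

Extracellular flux analyzers measure, in each well of a plate, the oxygen
consumption rate (OCR, pmol O2 min^-1^) and the extracellular acidification
rate (ECAR, mpH min^-1^) over repeated measurement cycles. OCR tracks
mitochondrial respiration (OXPHOS); ECAR is proportional to lactate
excretion and serves as a proxy for aerobic glycolysis. In the sperm assay
this package models, a run consists of 9 cycles of 6 minutes: cycles 1–4
untreated, a metabolic modulator injected before cycle 5 (oligomycin, FCCP,
2-deoxy-D-glucose, sodium oxamate, or plain medium for baseline wells), and
antimycin A + rotenone (A+R) injected before cycle 8. The residual OCR after
A+R is non-mitochondrial. The first cycle of a run is unstable and is
discarded from every computation; all aggregation is by cycle index
(`cycle_windows()`), never by clock time, although time is carried through
the files.

Each plate carries cell-free background wells. Background correction
subtracts, per cycle and per experiment, the mean background OCR and ECAR
from every measurement well. Corrected rates are then divided by the number
of sperm counted in the well and rescaled to amol O2 min^-1^ sperm^-1^ and
nano-pH min^-1^ sperm^-1^ (10^6^ amol per pmol and 10^6^ npH per mpH;
`units` arguments of `normalize_per_sperm()`). Correction precedes
normalization — the only dimensionally coherent order, since background
wells contain no sperm to normalize by. Negative corrected rates are
retained at this stage; exclusion decisions belong to the statistics layer.
"nano-pH" is treated as an opaque rate unit: no buffer-capacity conversion
to proton efflux is attempted, because bicarbonate-derived acidification
cannot be separated from glycolytic acidification in this assay.

## The bioenergetic parameter panel

All panel quantities are condition-A-minus-condition-B window arithmetic on
per-sperm rates, with baseline = mean of cycles 2–4, treatment = cycles 5–7,
A+R = mean of cycles 8–9:

* **Basal respiration** = baseline OCR − A+R OCR (per well).
* **Proton leak (%)** = (oligomycin-well treatment-window mean OCR − its A+R
  mean), as a percentage of the pair's basal respiration; **ATP-linked
  respiration (%)** is its complement, so the two sum to 100 exactly.
* **Maximal respiration (%)** uses the *maximum* OCR among cycles 5–7 of the
  FCCP well (the uncoupled peak is the quantity of interest, and the mean
  would dilute it with onset cycles); **spare capacity (%)** = maximal − 100.
* **Basal glycolysis** = baseline ECAR, uncorrected — no non-glycolytic
  acidification floor is subtracted, consistent with reporting basal ECAR
  as-is; **glycolytic reserve (%)** uses the *maximum* ECAR among cycles 5–7
  of the oligomycin well over basal glycolysis.
* **OCR/ECAR** is computed per well at baseline from uncorrected rates;
  cohort summaries average per-well ratios rather than dividing cohort
  means.

The max-value exceptions (FCCP OCR, oligomycin ECAR) apply identically in
both incubation conditions. Ties in a window max/min need no tie-breaking:
only the value is reported, never the cycle index of the extremum.

Quantities that need a basal reference pair each modulator well with the
baseline wells of the same experiment and condition. When several baseline
wells exist, `metabolic_panel()` computes all pairs and averages them per
modulator well (`pairing = "average"`, the default; `"first"` uses the first
baseline well in well-id order). Pairing maximizes data use; because the
percentage identities are affine in the pair values, the exact identities
(leak + ATP-linked = 100, spare = maximal − 100) survive the averaging. A
well pair whose basal respiration is not positive yields `NA` with a flag
rather than failing the plate, and a truncated run without an A+R window
falls back to uncorrected basal respiration with a `nonmito_uncorrected`
flag.

## Modulator responses

`response_percent()` expresses each well's treatment-window signal as a
percentage of its own baseline mean. For OCR, both the baseline and the
treatment aggregates are first corrected by subtracting the well's A+R-window
mean, so adding a constant to every OCR cycle of a well leaves the response
unchanged (a tested invariant). ECAR is not corrected. Two conventions are
provided: the within-species convention aggregates cycles 5–7 by the mean
for both signals; the interspecific convention keeps the OCR mean but uses
the ECAR maximum under oligomycin and minimum under 2DOG. `delta_percent` is
always `percent − 100`. Post-A+R ECAR responses use the cycles 8–9 mean
(aggregation `"mean_8_9"`) — the only window in which the A+R response
exists. Wells whose corrected baseline OCR is not positive are excluded
from response statistics (the gamma models downstream require positive
responses) and the exclusion is reported, making an implicit lab practice
auditable.

## Mixed-model inference

The observational unit is the well; the experiment (animal pool/plate)
enters as a random intercept, which is what licenses treating wells as
replicates while controlling between-experiment variability. Two families
are supported, both fit by maximum likelihood (never REML, so that
likelihood-ratio tests between fixed-effect structures are valid):

* `gaussian_log10` — a linear mixed model on log10(response);
* `gamma_inverse` — a gamma GLMM with inverse link, Laplace approximation by
  default, adaptive Gauss–Hermite quadrature behind the `nagq` argument for
  verification.

`lrt()` computes the chi-square statistic 2(ℓ_full − ℓ_reduced), clamped at
zero, with degrees of freedom equal to the difference in fixed-effect
parameter count. `choose_family()` fits both families and keeps the one
whose **deviance** residuals are closer to Gaussian by the Shapiro–Wilk W
statistic, with ties going to the Gaussian family. Deviance residuals are
used deliberately: the Pearson residuals of a correctly specified gamma fit
retain the response's skewness (≈ 2/√shape), so a Pearson-based criterion
systematically prefers the log-transformed Gaussian fit even on
gamma-generated data, whereas deviance residuals of a correct gamma fit are
approximately normal. `emm_contrasts()` delegates marginal means to
*emmeans* with equal weights over the other factors, Tukey adjustment by
default, Satterthwaite degrees of freedom for the LMM and the asymptotic z
approximation for the GLMM. `summarize_groups()` reports the mean, SD (n−1)
and a 95% t-interval half-width over wells, plus one over experiment means
(`ci_experiment`), since the two can differ materially in hierarchical data
and the reporting convention does not say which is meant.

Known calibration limits: with very few experiments (3–4 levels of the
random factor), the chi-square reference for the LRT on a fixed effect is
slightly anti-conservative; the measured type-I error at α = 0.05 in the
packaged null simulation (2 conditions × 4 experiments × 5 wells) sits near
the top of the 0.03–0.07 band. Boundary effects on the variance component
are handled by reporting singular fits with a warning flag rather than
failing.

## ATP quantification

`fit_standard_curve()` fits a per-plate least-squares line of luminescence
(RLU) against known ATP per well; luciferase signals integrated over a few
seconds are near-linear over the assayed range, so the linear form is the
default and a log-log form is available for multiplicative error. Curves
with r² below 0.98 are rejected with a diagnostic — everything downstream
inverts this line. `atp_per_sperm()` averages the replicate readings,
inverts the curve, and divides by the cells represented in the assayed
aliquot, giving amol sperm^-1^. Readings below the blank clamp to zero with
a flag; readings outside the standards' range are flagged as extrapolated
but kept, because the assays these data come from have small N and hard
rejection would discard whole conditions.

## The synthetic plate generator

`generator_config()` encodes the hierarchical process the analysis assumes.
For each well, the expected per-sperm rate at a cycle is

> condition mean × exp(experiment effect) × exp(well effect) ×
> treatment multiplier(cycle),

with the treatment multiplier approaching its plateau by a first-order onset
(default rate 0.776 per cycle, reaching 95% of the plateau by the second
post-injection cycle; the A+R block is treated as instantaneous, as complex
I/III inhibition is effectively immediate at these doses). Observed
per-sperm rates multiply the expectation by mean-one lognormal cycle noise;
raw well rates rescale by the simulated sperm count and add a Gaussian
background process that the cell-free wells measure alone. Cross-pathway
compensation is a static multiplier on the counterpart signal from the
injection cycle (ECAR rising under oligomycin; OCR rising — steppe-mouse
preset — or falling — house-mouse preset — under 2DOG), not a feedback ODE:
window statistics cannot distinguish the two, and mechanistic modeling is
out of scope. After A+R, ECAR takes a compensatory multiplier (default 1.4)
unless the well's glycolysis is inhibited (2DOG, oxamate), in which case the
treatment multiplier persists.

Defaults are anchored to the published cohort: condition basal means 315/231
amol O2 min^-1^ sperm^-1^ and 18.9/25.7 npH min^-1^ sperm^-1^; treatment
multipliers back-computed from the published percent responses through the
A+R-correction formula percent = (m − f)/(1 − f) with non-mitochondrial
floor f = 0.05 (oligomycin OCR 0.40, FCCP 8.0, 2DOG 1.5, oxamate 0.46; ECAR
1.5/0.7/0.63); between-experiment SD 0.35 on the natural-log scale, from the
published SD/mean ratio of basal respiration (~0.39 across experiments).
Well-to-well and cycle-to-cycle CVs (0.12 and 0.06) are not published
quantities; they are configuration choices at the level a well-behaved
plate assay shows, not claims. Multiplicative lognormal noise was chosen
because rates are positive and published dispersions scale with the mean —
the same reasoning that motivates the log10-LMM and gamma-GLMM analysis
families. One published inconsistency is worth noting: the published basal
OCR and ECAR means imply a basal OCR/ECAR ratio near 16.7 (NC), while the
published per-well ratio average is 5.19; both cannot be matched by any
generator with a common well-level rate scale, and the generator anchors the
basal means.

`generate_null_dataset()` draws equal-mean replicate datasets for
calibration studies, by default at the well-response level (the same
hierarchical lognormal the plate generator uses for its baseline window —
distributionally what the plate pipeline would deliver, at a fraction of the
cost), with full plate runs available via `level = "plate"`. Replicate seeds
derive deterministically from the master seed.

What passing the packaged simulations does and does not show: the generator
reproduces the design's hierarchical structure, positivity, multiplicative
noise, onset dynamics and compensation signs, so the tests validate the
window arithmetic, the panel algebra, exclusion rules and model calibration
under that structure. It does not emulate instrument drift within a cycle,
oxygen-diffusion physics, well-edge effects, counting error in sperm
numbers, or feedback between the pathways — conclusions about real plates
still require the diagnostics (`choose_family()` statistics, singular-fit
flags, exclusion logs) that the pipeline surfaces.

## Problem sizes and numerical choices

The packaged simulation studies use sizes at which their conclusions are
stable: 2000 replicates of 2 × 4 × 5 wells for LRT calibration, 200
datasets of ~200 wells × 8 experiments per family for parameter recovery,
1000 random 9-cycle traces for oracle equivalence (tolerance 1e-12
relative), and 6-experiment cohorts for pipeline recovery (2 SE criterion).
Window aggregation validates that every requested cycle is present and
errors otherwise; percent quantities are kept at full precision internally,
with integer rounding only in narrative report lines and one decimal in
tables. The pipeline writes a manifest whose config hash and seed fully
determine a rerun; all stage outputs are byte-identical on rerun (the
manifest's timestamp is the only exception).
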