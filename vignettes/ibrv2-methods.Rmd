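---
title: "Methods: from microplate readings to an integrated biomarker response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from microplate readings to an integrated biomarker response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrtox)
```

`ibrtox` analyses grouped multi-biomarker exposure studies: a control
group plus graded exposure concentrations, a battery of biochemical
endpoints per animal, and the two questions practitioners ask — which
endpoints respond, and how stressed is each group overall. This vignette
documents the models, the assumptions, the tunable parameters, and the
design decisions taken where more than one defensible choice existed.

## Assay reduction

Kinetic assays (AChE-, SOD-, GST- and ETS-type schedules) are reduced to
the ordinary-least-squares slope of optical density against time,
reported per minute (`kinetic_rate()`). All reads are used — there is no
automatic lag-phase trimming, because read schedules of a few minutes at
30–60 s intervals rarely resolve a lag reliably; users who need trimming
can subset the trace before fitting. The slope is invariant to a constant
baseline offset and preserves sign, so substrate-depletion assays come
out negative.

Blank correction subtracts the *mean* signal (or mean rate) of all
procedural-blank wells of a run. Replicates — triplicates by default —
are averaged, and a coefficient of variation above 20% flags the sample
(`cv_threshold`, configurable; 20% is common plate-assay practice rather
than a derived constant). A single replicate has an undefined CV and is
reported as missing, not flagged.

Endpoints are standardised to the protein content of each homogenate and
reported in blank-corrected, protein-normalised signal units (OD/min/mg
or OD/mg). We deliberately do not convert to international enzymatic
units: every downstream statistic in the package — rank tests, the
normality cascade, standardisation, IBRv2 — is invariant to a
per-biomarker linear rescaling, so extinction-coefficient conversions
would change no reported result. For the same reason SOD is treated as a
plain kinetic rate; the percent-inhibition transformation used in some
dismutase protocols is a per-assay monotone rescaling that the downstream
analysis does not see.

Missing values (an animal missing an assay) propagate as missing and are
never imputed; group sizes may therefore differ across biomarkers, as
they commonly do in practice.

## Cellular energy allocation

`Ea = Eprot + Eglu + Elip` and `CEA = Ea − Ec`, both computed exactly in
whatever common energy-equivalent unit the reserves arrive in. An
optional conversion-factor vector (`add_energy_budget(conversion = ...)`,
defaults all 1) lets users with calorimetric calibrations convert
reserves before summing; the package does not assume any particular
enthalpy-of-combustion constants. Negative CEA is meaningful
(consumption exceeding reserves) and preserved. A missing component makes
that animal's budget missing rather than raising an error.

## The group-comparison decision tree

For each biomarker, `compare_groups()` executes:

1. **Normality.** Shapiro–Wilk per group at α = 0.05. The data "conform"
   only if *every testable group* passes. Per-group testing (rather than
   pooled model residuals) is the stricter and simpler reading, and the
   per-group p-values are recorded in the decision trail so the call can
   be audited. Groups with n < 3 cannot be tested and do not block the
   pass; a constant-valued group fails with a degeneracy flag.
2. **Transform cascade.** Failing data are square-root transformed and
   retested, then natural-log transformed and retested; the first
   passing transform is kept. The sqrt branch requires non-negative
   values and the log branch positive values; inapplicable branches are
   skipped.
3. **Homogeneity.** If normality is met, Levene's test with
   `center = "mean"` (the classical form; `"median"` gives
   Brown–Forsythe) at α = 0.05 routes to either the classical one-way
   ANOVA with Tukey's HSD, or Welch's ANOVA with the Games–Howell post
   hoc. Tukey uses pooled-variance Tukey–Kramer standard errors;
   Games–Howell uses per-pair Welch–Satterthwaite degrees of freedom and
   the studentized-range distribution.
4. **Rank branch.** If normality fails after both transforms, the
   Kruskal–Wallis H (tie-corrected) with Dunn's pairwise z tests and a
   Bonferroni correction (capped at 1) is applied to the *original*
   values: rank statistics are invariant under the strictly monotone
   sqrt/ln transforms, so running them on transformed values would be
   cosmetic.

Effect sizes follow the omnibus family: ω² = df₁(F−1)/(df₁(F−1)+N) with
N = df₁+df₂+1 for the F branches, ε² = H/(n−1) for the rank branch.
Negative values (F < 1) are reported as computed; clipping them at zero
would hide how far below its null expectation a statistic fell. On the
Welch branch ω² is computed with the nominal df₁ and the actual total N
and flagged `effect_size_approx`: there is no exact small-sample ω² for
Welch's F, and the flag keeps the approximation visible.

Post hocs are run regardless of omnibus significance by default
(`posthoc_if_significant = FALSE`), because pairwise tables alongside a
modest omnibus p are standard reporting practice in this field; gating is
one switch away. The significance threshold is fixed at α = 0.05
throughout, with p < 0.01 additionally marked in the report.

No multiple-testing correction is applied *across* biomarkers: the
per-biomarker results are descriptive endpoints of a battery, and
integrating them is the job of the IBRv2 score, not of a family-wise
error rate.

## IBRv2

For biomarker *b* with values `X` over all animals:

* `Y = ln(X / mean(X_ref))` by default (`log_mode =
  "log_ratio_to_reference_mean"`). The plain `ln(X)` variant is provided
  because study write-ups often say only "log-transformed"; the two give
  *identical* deviation indices — the reference-mean factor is a
  per-biomarker constant that cancels in standardisation — and the test
  suite asserts this, so the choice is presentational.
* `Z = (Y − mean(Y)) / sd(Y)`, mean and SD over the full data set (all
  groups pooled), sample SD (n−1). Population vs sample SD rescales each
  biomarker's Z by a common factor and then cancels in A only when group
  sizes are equal per biomarker; the choice is therefore recorded in the
  result (`sd_mode = "sample"`).
* `A(g,b) = mean(Z | group g) − mean(Z | reference)`; positive =
  stimulated, negative = inhibited relative to the reference. The
  reference row is identically zero.
* `IBRv2(g) = Σ_b |A(g,b)|`, with missing cells excluded pairwise and
  the count of contributing biomarkers reported alongside the score.

The log base is configurable and provably irrelevant to A (another
common-factor cancellation, also asserted in tests). Non-positive values
are an error unless a `zero_offset` is supplied; silently offsetting
would change results without the user noticing. `radar_data()` exposes
the signed-A polygons (fixed biomarker order, zero baseline ring) that
the conventional radar plots draw.

## The synthetic-study generator

`study_design()` defaults encode the design the analysis targets: four
groups at exposure fractions 0 / 0.25 / 0.5 / 1, 20 animals per group,
and a 12-endpoint battery (`default_biomarker_panel()`). Defaults for
the panel are the package's own choices of realistic assay behaviour:
positive right-skewed endpoints (lognormal family), coefficients of
variation 0.2–0.35, and effect sizes of 1.5 within-group SDs at full
strength for the endpoints designed to respond (AChE, SOD, GST inhibited;
CAT, MDA, glucose energy stimulated; GSH and Ec at 1.0 SD; MT, PC,
protein and lipid energy null). Effects scale linearly with the exposure
fraction and act on the log-scale mean, i.e. multiplicatively on the
median. A normal family (additive effects) exists to exercise the
parametric branch; it rejects parameterisations that can produce
non-positive values rather than truncating them. Per-group dropout
probabilities reproduce unequal group sizes.

Plate emulation (`generate_plate()`) wraps each designed endpoint in the
raw-data structure the assay module consumes — triplicate wells, blank
wells, kinetic ramps at the biomarker's read schedule — so the reduction
chain can be round-tripped: with zero read noise the designed values are
recovered exactly (to floating-point), and blank offsets cancel.

What the generator does *not* emulate: correlated biomarkers (draws are
independent given the design), tank/replicate random effects,
concentration-response nonlinearity (effects are linear in the fraction),
heavy-tailed outliers, or plate-position artefacts. Passing tests
therefore demonstrate that the pipeline recovers the truth *under its own
distributional assumptions*, not that real fish data meet them.

## Calibration and problem sizes

The test suite calibrates the engine at the study's natural scale:
type-I error of the omnibus decision tree under a 4-group × 20-animal
null over 1000 replicates (required within 5% ± 2 points on the
parametric branch), detection power for the 1.5-SD designed effects at
n = 20 over 200 seeds (required ≥ 90% per endpoint), and IBR-vs-dose
monotonicity over the same 200 seeds (required ≥ 90%). These sizes give
binomial standard errors comfortably inside the required bands while
keeping the whole suite around a minute on one core.

## Numerical notes and degenerate inputs

* Slope fitting uses the centred closed form; a brute-force
  normal-equations solve is the test oracle.
* Tukey/Games–Howell p-values come from `ptukey`; pairs with zero
  estimate report p = 1, and an all-constant pair is p = 1 (Tukey) or an
  error naming the pair (Games–Howell, whose statistic is undefined
  there).
* Kruskal–Wallis on all-identical data reports H = 0, p = 1 with a
  degeneracy flag instead of 0/0; the same situation in Dunn's variance
  term yields z = 0, p = 1.
* Levene on fully constant groups reports a flagged p = 1; groups with
  n < 2 are excluded with a warning.
* ω² from the F form and from raw sums of squares agree to 1e-12 (an
  algebraic identity, asserted on exact fixtures).
* All tie-breaks are deterministic: identical inputs give identical
  decision trails, and pipeline reruns with the same config and seed are
  byte-identical.

## Known limitations

* The Welch-branch ω² is approximate (flagged as such).
* The IBRv2 score aggregates absolute deviations, so it cannot
  distinguish a group with many small responses from one with a few
  large responses of mixed sign; the signed A matrix and radar data are
  the disaggregated view.
* Two-way and repeated-measures designs are out of scope; the engine is
  strictly one-factor.
* The package computes no bioaccumulation or water-chemistry statistics;
  leachate element tables are only tabulated and ranked.
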