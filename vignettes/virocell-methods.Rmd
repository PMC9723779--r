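---
title: "Models and methods behind virocell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind virocell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virocell)
```

`virocell` packages the quantitative spine of a factorial phage × protist ×
cyanobacteria co-culture experiment: four treatments (untreated control,
+phage, +protist, +phage+protist), four biological replicates, six
sampling timepoints between 2 and 12 h post addition. This vignette
explains each model, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the procedure was genuinely open.

## Infection statistics

The multiplicity of infection is the ratio of infectious phage to host
cells at inoculation, `MOI = P / mean(H)`. The host term averages the
phage-bearing treatments' densities *during the infection incubation*
(defaults 2.8×10⁷ and 2.9×10⁷ cells mL⁻¹), not the post-wash start-of-
experiment densities (1.7–2.2×10⁷ cells mL⁻¹): cells are washed free of
unadsorbed phage after one hour, so the MOI is set by the pre-wash
densities. The design object carries both (`inoculation_host_concs` vs
`start_concentrations`). MOI is reported rounded to one decimal.

Assuming phage adsorb independently, the number of phage per cell is
Poisson with mean MOI, and the infected fraction is `1 − exp(−MOI)`.
Percentages are reported to the nearest whole percent. With the default
concentrations this chain gives MOI 1.1 and 67% infected — recomputed, not
stored, by `scripts/acceptance.R`.

Predator–prey encounters use the standard bilinear kernel
`E = β · C_predator · C_prey`. The cruising-predator clearance rate
`β = π R² v` (contact radius R, relative speed v, converted from µm to
mL s⁻¹) is the default model, but β can be supplied directly because
published encounter rates are usually calibrated from parameters that are
not printed alongside them; a calibrated β ≈ 6.07×10⁻⁷ mL s⁻¹ reproduces
an encounter rate of ≈444 prey mL⁻¹ s⁻¹ at 43 predators and 1.7×10⁷ prey
per mL. The cumulative encountered fraction offers a linear
(with-replacement, capped at 1) and an exponential (without-replacement)
model; the exponential is never above the linear one. We deliberately do
not attempt to reproduce any particular published cumulative-percentage
range from these inputs: under either model the arithmetic from the rate
and prey density alone does not reconstruct such ranges, which depend on
unpublished parameterization choices.

Start-vs-end abundance decline is a two-tailed two-sample t-test. Welch's
unequal-variance form is the default — with n = 4 per group and no reason
to assume equal variances it is the safer reading of "a t-test" — and the
pooled-variance Student form is available by flag.

## MPN titer estimation

A dilution series scores wells positive/negative; under the single-hit
Poisson model a well at dilution d and volume v is positive with
probability `1 − exp(−c d v)`. `estimate_mpn()` maximizes the binomial
log-likelihood over `log10(c)` on the bracket [−6, 12] with Brent-style
optimization to 10⁻⁶ tolerance, rather than using classical MPN lookup
tables — the tables are a discretization of the same likelihood and do not
extend to arbitrary 96-well schemes. The 95% CI is Wald on `log10(c)` from
the observed information (titers span decades, so the log scale is the
right one), with a profile-likelihood fallback when the curvature is
degenerate or the Wald interval escapes the bracket. All-negative plates
return a zero estimate with an upper bound only; all-positive plates a
lower bound only. `pool_series()` sums wells across independent series
sharing a dilution scheme; the pooled likelihood is the product of the
per-series ones, so the pooled CI is narrower than any single series'.

## FRRf photophysiology

Fast repetition rate fluorometry delivers 100 sub-saturating excitation
flashlets on a 2-µs pitch (saturation phase) then 40 on a 50-µs pitch
(relaxation), five sequences per acquisition. Each flashlet closes a
fraction σ of the still-open PSII reaction centres:

    C_0 = 0,  C_{i+1} = C_i + σ (1 − C_i),  F_i = Fo + (Fm − Fo) C_i

This is a reduced single-turnover induction form without inter-PSII
connectivity. It was chosen because only Fo and Fm are consumed
downstream, it is exactly invertible on noiseless traces (the test suite
checks the round trip to 10⁻⁴), and adding connectivity would add a
parameter the data cannot constrain at this noise level. Fitting is
nonlinear least squares (Levenberg–Marquardt) per sequence with parameters
averaged across sequences; Fo and Fm come from the fit, not from the raw
minimum/maximum, for robustness to instrument noise. Relaxation flashlets
are recorded for format fidelity but not used in Fo/Fm estimation. Blank
correction subtracts the paired cell-free trace (per flashlet) or a scalar
blank, flooring at zero with a warning count.

`fv_fm()` is `(Fm − Fo)/Fm`, guarded: `Fm ≤ 0` and `Fo > Fm` are errors
flagging a failed fit. Treatment comparisons are Welch t-tests per
timepoint against a baseline, with percent change of replicate means.

## Differential metabolomics

The procedure, applied independently per compartment (intracellular
endometabolome, dissolved exometabolome), per treatment, per timepoint:

1. **Detection filter** — a feature enters a comparison group only if its
   raw peak height is ≥ 10,000 in ≥ 2 biological replicates of that group;
   the rule is evaluated per comparison group (the across-experiment
   alternative is configurable, as the published wording is ambiguous).
2. **log₁₀ transform** — retained heights are log₁₀-transformed.
   Sub-threshold cells default to imputation at threshold/2 (= 5,000)
   before the log; `impute_threshold` and `drop` policies are available.
   The half-threshold default treats a missed detection as "somewhere
   below the limit" without zero-inflating the test scale.
3. **Dual significance threshold** — `log10_fc` is the difference of
   replicate-averaged log₁₀ heights (treatment − control); p from a
   two-tailed Welch t-test on the log scale; BH adjustment across all
   retained features within one (treatment, timepoint, compartment)
   family — the narrowest family consistent with time-matched comparisons,
   and configurable since wider families are defensible; significant iff
   `|log10_fc| ≥ 0.1` (boundary inclusive) and `fdr ≤ 0.05`.

The threshold applies to the *absolute* fold change: depleted metabolites
are as reportable as enriched ones, which is the only reading consistent
with reporting depleted compounds as significant. The 0.1 threshold on
log₁₀ corresponds to `(10^0.1 − 1) × 100 ≈ 25.9%` on the raw scale.

Annotation confidence follows the three-criterion rule: retention-time,
m/z, and MS/MS matches all present → level 1; exactly two → level 2;
otherwise the feature is unidentified ("Other").

## Differential transcriptomics

RPKM is used (not TPM/CPM) because the downstream displays are defined on
log₂RPKM; the library size is the total counts of the supplied matrix, and
a pseudocount of 1 precedes the log. DE calls mirror the metabolite
procedure on the log₂RPKM scale with defaults `|log₂FC| ≥ 1`,
`FDR ≤ 0.05`, BH per (treatment, timepoint) family. This is a transparent,
self-contained procedure; no claim is made that it reproduces any
particular published DE gene list, since those derive from unpublished
custom scripts and raw reads that this package deliberately does not
consume.

Phage temporal classes: per-gene log₂RPKM time series are standardized
across timepoints (z-scores; constant genes become zero rows and are
flagged), and each gene is classed early / middle / late by the tercile of
the first infection-cycle window (default 2–8 h, matching the ~6–8 h
latent period) containing its peak, ties resolved toward the earlier
timepoint. Class switches between conditions are flagged. Category
summaries report, for significant genes in a category at a timepoint, the
gene count and `aFC = mean(2^|log2_fc|)` with the regulation direction
tallied separately, so a single gene's aFC is exactly `2^|log2_fc|`.

## What the generator emulates — and what it does not

`simulation_config()` defaults *are* the study conditions: 4×4×6 design,
host ~2×10⁷ cells mL⁻¹ (1.9/1.7/2.2/1.7 ×10⁷ by treatment), phage 3×10⁷
pfu mL⁻¹, protist 43 cells mL⁻¹, latent period 6–8 h, detection threshold
10,000, control Fv/Fm 0.30 (the healthy range is ~0.27–0.33) with a 35%
infection reduction at 2 h deepening to 64% by 12 h and a 15% relative
recovery in the phage+protist arm near 5 h.

- **Abundances**: uninfected hosts grow slowly (0.01 h⁻¹); infected hosts
  hold their start density through the latent period then decline linearly
  to a `decline_fraction` (default 0.5) by 12 h; free phage rise after the
  latent period by `burst_size` (default 4 — a deliberately simplified
  figure, exposed as a free parameter, not calibrated) per lysed cell;
  protists stay constant. Replicate noise is multiplicative lognormal
  (CV 5%, a typical flow-cytometry spread).
- **Counts**: negative binomial (dispersion 0.05, mid-range for bulk
  RNA-seq) around treatment×timepoint means, lognormal library-size
  factors clamped within 2-fold, phage genes structurally zero in
  phage-free arms, spiked genes shifted by `2^log_fc`. Phage temporal
  bumps peak at 2/6/8 h for early/middle/late — deliberately *on* sampled
  timepoints, because a peak midway between samples produces an exact
  standardized tie that the earlier-timepoint tie-break would resolve to
  the wrong tercile; real instruments do not sample on a 2-h grid relative
  to unknown true peaks, so class-recovery rates on these synthetic data
  are an upper bound.
- **Features**: Gaussian log₁₀ peak heights (SD `peak_sigma`, default
  0.1) around per-feature means uniform on [4.3, 6]; spiked features shift
  the log₁₀ mean; 2% of cells are censored to zero to emulate missed
  detection; annotation flags drawn so all three confidence levels occur.
- **FRRf**: exact closure-model traces plus additive Gaussian noise and a
  paired blank; the true Fv/Fm of each acquisition is the configured mean
  plus replicate-level variation, recorded in the truth table.
- **MPN plates**: independent Bernoulli wells at the exact single-hit
  probabilities.

Not emulated: mechanistic intracellular infection kinetics, grazing
functional responses (protist abundance is constant, as observed at this
predator:prey ratio), mass-spectral structure, read-level sequencing
artifacts, and between-timepoint autocorrelation of noise. Passing tests
on these data therefore demonstrate correctness of the *procedures* and
their calibration (FDR control, type-I error, estimator consistency), not
robustness to every pathology of real instruments.

Every generator draws through a deterministic stream derived from
`(seed, stage)`, so identical configs give byte-identical outputs and the
compartments do not share randomness. The seed is mandatory; there is no
hidden global state.

## Statistical power of the dual-threshold procedure

A point worth making explicitly, because it constrains what any validation
of this procedure can promise. At the per-feature settings
|log₁₀FC| = 0.3, n = 4 per arm, log₁₀ SD = 0.1, the Welch statistic has
noncentrality ≈ 4.24 with ≈ 6 degrees of freedom, so the per-test power
ceiling at α = 0.05 is ≈ 0.94. Under BH, the effective per-test threshold
scales with the *fraction of truly changed features in the family*: with
10% spiked in a 500-feature family the effective threshold is ≈ 0.005 and
the realized power ≈ 0.1; even a half-spiked family equilibrates near
0.74. Recovery power ≥ 0.8 is therefore not attainable for this effect
size and replication under any realistic family composition — a property
of the t distribution at n = 4, not of the implementation (an independent
textbook-formula reference gives the same numbers). The package's test
suite documents this honestly: the FDR-control and effect-size-recovery
checks pass, and the corresponding power expectation is asserted at the
stated composition and fails, by design visible rather than silently
relaxed. Practitioners wanting 0.8 power at a 25% metabolite change should
plan for more replicates (n ≈ 8 brings the per-test ceiling at the
BH-adjusted threshold above 0.9) rather than trust a 4-replicate design.

## Numerical choices and degenerate inputs

- MPN: optimization bracket log₁₀c ∈ [−6, 12], tolerance 10⁻⁶;
  `log(1 − exp(−λ))` computed via `log1p` with a series guard for tiny λ.
- Induction fits: starting values from the first flashlet (Fo), the trace
  maximum (Fm) and σ = 0.05; bounds keep σ ∈ (0, 1]; a flat trace is
  returned as Fm = Fo (Fv/Fm = 0) without invoking the optimizer;
  non-convergent sequences are flagged, never silently replaced.
- Zero-variance t-test cells: identical groups give p = 1; exactly
  separated constant groups give p = 0 — both bypass the t machinery,
  which is undefined there.
- BH ties are broken by entity id for deterministic output order.
- Venn regions are labelled by sorted set labels joined with `&`, so
  counts are invariant to input order.
- Floats in TSV outputs are written at 15 significant digits so
  writer/reader round trips are lossless to 12 digits.

## Problem sizes used in the test suite

Module tests run on deliberately small instances — tens of genes or
features, 20–100 seed ensembles, a 10⁴-simulation type-I-error check, a
400-simulation MPN consistency check at 96 wells — chosen as the smallest
sizes at which the assertions are statistically meaningful for the stated
tolerances. The acceptance checks use the full stated compositions (e.g.
100 seeds × 500 features for the FDR target).

## Known limitations

- The encounter module reproduces printed encounter rates only through a
  calibrated clearance rate; it does not claim to derive unpublished
  kernel parameters.
- The DE procedure is a transparent stand-in for unpublished custom
  analysis scripts; its counts are not expected to match any particular
  published tally.
- MPN confidence intervals are asymptotic (Wald/profile); exact
  small-sample coverage is not guaranteed for plates with very few wells.
- The induction model omits PSII connectivity and relaxation kinetics;
  σPSII is reported in per-flashlet units, not physical cross-sections.
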