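# clonedyn

Clonal hematopoiesis (CH) — the age-related expansion of blood-cell
clones carrying somatic driver mutations — is usually summarized by a
single VAF snapshot. `clonedyn` is for researchers with *longitudinal*
deep-sequencing data: it turns each participant's variant allele
frequency (VAF) trajectories into an inferred clonal structure, a
per-clone fitness estimate, and a per-mutation acquisition age, and
carries those quantities into survival and blood-marker association
analyses.

## The model in brief

A mutant clone acquired at age `ATMA` grows exponentially at its net
fitness `s` (per year), `x(t) = exp(s (t − ATMA))`, against a fixed pool
of `N = 100,000` wild-type stem cells. A heterozygous variant is observed
at

    VAF(t) = x(t) / (2 (N + x(t)))            (isolated growth)

which saturates at 0.5, or — when several clones compete for the same
compartment — at

    VAF_j(t) = x_j(t) / (2 (N + Σ_b x_b^lead(t)))   (mutational context)

summing the lead-variant size of every clone `b`. Read counts are
binomial around the model VAF. For each participant, every partition of
their variants into clones is scored by grid-based marginal likelihood
(uniform prior on fitness, acquisition ages profiled); the
maximum-evidence structure yields MAP fitness per clone, maximum
likelihood ATMA per variant, and

    MACS120 = exp(s (120 − ATMA))

the predicted clone size at the maximum human life span — a single
growth-potential metric combining fitness and timing.

The package also ships a synthetic-cohort generator with known ground
truth (three longitudinal sampling designs, gene-category fitness
profiles, binomial read noise, mixed-model marker trajectories,
proportional-hazards survival), variant-level filters (AO/UAO, gnomAD,
germline-stability), co-occurrence network summaries with
Brunner–Munzel tests, and the downstream linear-mixed-model and Cox
stages with adaptive FDR control.

## A worked example

```r
library(clonedyn)
set.seed(7)

cohort <- simulate_cohort("LBC", 30)              # 3 waves near ages 70/76/82
filt   <- apply_variant_filters(cohort$variants)  # AO/UAO, gnomAD, germline
parts  <- build_trajectories(filt$kept, covariates = cohort$covariates)
fits   <- ch_fit_cohort(parts)

print(fits[[2]])
#> Clonal dynamics fit for participant LBC_0003
#>   1 variant(s) in 1 clone(s); log evidence -10.308
#>   clone 1: {PPM1D:vPPM1}  s_MAP = 0.130 (lead PPM1D:vPPM1)

coef(fits[[2]])
#>       variant clone    s     atma  macs120 log_macs120
#> 1 PPM1D:vPPM1     1 0.13 18.84599 514021.7    13.15002

cmp <- compare_isolated_vs_context(fits, t = 120)
cmp$summary
#> $mean_abs_delta
#> [1] 0.07246927
#> $frac_participants_over
#> [1] 0.2
```

The fit says: this participant's PPM1D variant expands at ~13% per
year, was acquired around age 19, and would reach ~5 × 10^5 cells by
age 120 if unopposed. Across this simulated cohort, accounting for
competition between clones shifts the mean predicted VAF at age 120 by
~0.07, and 20% of participants shift by more than 0.20 — competition
matters most for participants carrying several strong clones. `plot(fits[[i]])` overlays the
observed trajectory with the competition-aware (solid) and isolated
(dashed) forecasts; `summary()` adds posterior fitness intervals per
clone.

## Vignette

`vignettes/clonal-dynamics.Rmd` documents the model and its assumptions,
the inference scheme and its two deliberate simplifications, what the
synthetic generator does and does not emulate, and the package's
numerical conventions.
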