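---
title: "Modelling clonal hematopoiesis dynamics from longitudinal VAF trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clonal hematopoiesis dynamics from longitudinal VAF trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedyn)
```

## The model

Clonal hematopoiesis (CH) is the age-related expansion of blood-cell
clones carrying somatic driver mutations. `clonedyn` infers, from a
participant's longitudinal variant allele frequency (VAF) measurements,
three quantities per mutation: the clone's **fitness** `s` (net per-year
proliferative advantage), its **clonal structure** (which mutations share
a clone), and its **ATMA** (age at the time of mutation acquisition, the
most probable past age at which the clone was a single cell).

The latent model is a supercritical birth-death process over hematopoietic
stem cells. Its expectation — and the deterministic skeleton we fit — is
exponential growth from one cell:

$$x_j(t) = e^{s_j (t - \mathrm{ATMA}_j)}, \qquad t \ge \mathrm{ATMA}_j ,$$

against a fixed wild-type pool of $N = 100{,}000$ stem cells. A
heterozygous mutation in a diploid genome is carried on one of two
chromosome copies, so the *isolated-growth* VAF is

$$\mathrm{VAF}(t) = \frac{x(t)}{2\,(N + x(t))},$$

which saturates at $0.5$ once the clone dwarfs the pool. When a
participant carries several clones they compete for the same compartment;
the *context-aware* VAF of variant $j$ divides by every clone's
lead-variant size:

$$\mathrm{VAF}_j(t) = \frac{x_j(t)}{2\,\bigl(N + \sum_b x^{\mathrm{lead}}_b(t)\bigr)} ,$$

where the sum runs over the clones $b$ of the selected structure and the
lead of a clone is its highest-VAF variant (the carrier lineage whose size
proxies the clone's contribution to the pool). The diploid factor 2 is not
optional decoration: it is what makes the isolated model saturate at VAF
0.5 rather than 1, and every prediction in the package uses it.

Two derived metrics summarize a clone's clinical potential:

* `MACS120` $= e^{s (120 - \mathrm{ATMA})}$, the predicted clone size at
  the maximum human life span; its logarithm $s(120-\mathrm{ATMA})$ is the
  scale used for regression covariates, because the raw value spans tens
  of orders of magnitude and a linear z-score would be dominated by the
  single largest clone.
* the per-variant difference between isolated and context-aware VAF
  forecasts at age 120, which quantifies how much clonal competition
  suppresses a mutation's apparent growth.

## Inference

For $k$ variants, every set partition into clones is a candidate
structure (`enumerate_structures()`; Bell numbers $1, 2, 5, 15, \dots$,
exhaustive up to $k = 8$, greedy agglomerative merging above). Variants in
one clone share a single fitness; each variant keeps its own acquisition
age, with non-lead variants constrained to be acquired no earlier than
their clone's lead (a subclone arises inside an existing clone).

Given a structure, read counts are modelled binomially:
$\mathrm{AO}_{jt} \sim \mathrm{Binomial}(\mathrm{depth}_{jt},
\mathrm{VAF}_j(t))$, with a sequencing-error floor VAF of $10^{-4}$ for
ages before acquisition. Fitness is scored on a uniform grid
($[0, 1]$ in steps of $0.005$ by default) with a uniform prior;
acquisition ages are profiled out on a 1-year grid. The evidence of a
structure is its grid-summed marginal likelihood, and the structure
maximizing evidence is selected (`ch_fit()`), with ties broken toward
more independent clones and then canonical order.

Two deliberate simplifications relative to a full joint treatment are
worth stating:

* **Within-block competition only during fitting.** The fitted emission
  for a clone uses the denominator $N + x^{\mathrm{lead}}_b$ of that clone
  alone, so evidence factorizes over clones and the posterior for each
  clone is an independent grid sum. Cross-clone competition enters at the
  prediction stage (`predict_context()`), once each clone's parameters
  are known. A fully joint denominator would couple every clone's fitness
  and acquisition grids and is combinatorially infeasible exactly; at the
  VAFs where structure inference is actually informative (clone sizes
  well below $N$) the two denominators are nearly identical.
* **Profiling, not marginalizing, acquisition ages.** ATMA behaves as a
  nuisance level parameter during structure scoring; profiling matches
  the downstream convention of estimating ATMA after fixing the MAP
  fitness. Marginalization is a one-line change but makes evidence
  depend on the arbitrary ATMA grid range, so the default profiles.

After structure selection, `estimate_atma()` re-estimates each variant's
acquisition age by continuous maximum likelihood (tolerance $10^{-6}$
years) under the isolated model at the clone's MAP fitness, bounded to
$[0, \text{first observation age}]$: near-birth acquisition is allowed
(epigenetic-regulator mutations are routinely dated to early childhood)
but prenatal ages are not emitted; boundary optima are clamped and
flagged.

ATMA is unidentifiable at $s = 0$ (a neutral clone has no growth curve to
date) and is returned missing there.

## What the synthetic generator emulates

`simulate_cohort()` produces cohorts with known ground truth under three
sampling designs: three waves near ages 70/76/82 (a birth-cohort design),
five waves over twenty years, and a design enrolling women aged 50–79
with visits at years 1/3/6/9 plus one late-life visit. Sequencing depth
is negative-binomial around template means of 2000/1000/1500; the
template depths are placeholders (the source studies do not publish
depths) and are exposed in the design lists. Read noise is binomial
around the context-aware model VAF. Fitness is drawn log-normally around
functional-category means (splicing genes highest at 0.20, epigenetic
regulators lowest at 0.09, signalling/transcription/chromatin between),
a spread chosen for realism only — no calibration claim attaches to it.
Acquisition ages are placed so clones are detectable by the first visit,
emulating a carrier cohort that passed a VAF ≥ 1% detection filter.

The stochastic mode (`simulate_clone(..., mode = "birth_death")`) runs a
Gillespie simulation with per-cell birth rate $1 + s$ and death rate $1$
per cell-year — the data identify only the net rate $s$, so this choice
fixes the noise timescale — rejection-conditioned on non-extinction by
the first sample age, since clones observed in data necessarily
survived. Above $10^5$ cells demographic noise is negligible and growth
is advanced deterministically.

What the generator does **not** emulate: sequencing artifacts and
UMI/error-correction structure, cohort attrition beyond independent
censoring, time-varying fitness, and clone interactions beyond shared-pool
competition. Passing recovery tests on this generator therefore
demonstrates internal consistency of the estimator, not robustness to
real-data artifact structure.

## Variant filtering

`apply_variant_filters()` encodes the study-style call-level rules: a
variant qualifies if at any visit it has VAF ≥ 1% (2% selectable),
AO ≥ 5 supporting reads, UAO ≥ 3 unique starts (when available), and a
gnomAD under-representation p ≤ 0.05 (when available); once a variant
qualifies anywhere, all its participant-matched visits are kept, so
trajectories retain sub-threshold early points. Variants pinned near VAF
0.5 or 1.0 at every wave are rejected as germline; the stability band
(±0.05) absorbs binomial noise at typical depths — the underlying rule
states the levels, not a tolerance, so the band is ours. Manual-curation
steps (artifact lists, database cross-referencing) are represented as
allow/deny lists rather than re-implemented heuristics, because they were
human judgment in the original workflow. A quantitative directional-bias
(strand) test is not part of the rule set here; only the AO/UAO
thresholds are applied.

## Downstream association stages

*Blood markers.* Within each cohort, a marker series is fenced at
$Q_1 - 3\,\mathrm{IQR}$ / $Q_3 + 3\,\mathrm{IQR}$, transformed by
whichever of identity, log, square root, Box–Cox, or Yeo–Johnson
maximizes the Shapiro–Wilk W (the selection criterion "as normal as
possible" needs an operational statistic; W is the default, λ chosen on a
grid from −2 to 2), then z-scored; binary markers pass through untouched.
`fit_marker_lmm()` fits `marker ~ age * maxVAF + maxFitness + MACS120`
with a participant random intercept; the `age:maxVAF` coefficient carries
the rate-of-change reading, and age interactions for the other two
metrics sit behind `extra_interactions` because the default formula is
fitted exactly as printed. P-values are adjusted per predictor across the
marker panel by the two-stage (adaptive) Benjamini–Hochberg procedure;
its adjusted values are clamped to be no smaller than the raw p so the
output invariant `p_adj >= p` holds even when the adaptive scaling is
favorable.

*Survival.* `fit_cox()` fits a proportional-hazards model with z-scored
maximum VAF, maximum fitness, age at first observation, sex, and
log-scale MACS120, reporting log proportional hazards, 95% CIs and the
concordance index, with optional refits per cohort and per age bin
(half-open bins `[50,60) [60,70) [70,80) [80,∞)`). Monotone-likelihood
separation triggers a flagged ridge-penalized refit; constant covariates
are dropped with a warning.

*Co-occurrence.* `build_network()` summarizes which genes (or functional
categories) share clones, with node size `log(count)` and node color the
mean log fitness rescaled to `[0, 1]` (0.5 when all nodes coincide);
`compare_isolated_vs_cooccurring()` contrasts log fitness of
alone-in-clone versus co-occurring variants per group with the
Brunner–Munzel test and Benjamini–Yekutieli correction across all tests
performed. Whether the correction universe should span genes, categories,
or both at once is ambiguous; the package corrects within the grouping
requested in the call. Groups with under 2 observations per arm are
reported descriptively and excluded from correction, and fitness at the
grid minimum is floored at half a grid step before logging.

## Numerical choices and degenerate inputs

* Likelihoods use a continuity-tolerant binomial form (the combinatorial
  term is constant in the success probability), so noiseless fixtures can
  carry exact expected counts.
* Evidence sums run in log space (`logsumexp`); probabilities are clipped
  to $[10^{-12}, 1 - 10^{-12}]$ before logging.
* Zero-depth observations are skipped with a warning; all-zero-read
  trajectories yield a flagged, missing ATMA; an empty trajectory set has
  log-likelihood 0.
* ATMA is numerically identifiable only between the detection floor and
  VAF saturation: a trajectory pinned at ~0.5 (or below ~2 reads) is flat
  in acquisition age at double precision, and the estimate there is only
  as good as the flat region is narrow. The ATMA objective omits both the
  error floor (so a single-cell observation dates acquisition to the
  observation age exactly) and the combinatorial constant (whose
  magnitude would swamp the informative terms for weakly identified
  trajectories).
* Evidence ties (exactly equal within $10^{-9}$) select the partition
  with more clones — the less committal hypothesis — then canonical
  restricted-growth order, and the tie is recorded on the fit.

## Problem sizes used by the test suite

The recovery studies in the package's tests run at the scale a reviewer
can reproduce on a laptop: 200 replicates per condition for
fitness/ATMA recovery (4 waves at ages 80–95, depth 2000; first-visit
VAF 0.5%), 200 replicates per two-variant design for structure
classification, 60–100 replicates for mixed-model and Cox
coverage studies (n = 300 and 700 participants), and a 20-replicate
43-marker null panel for FDR calibration. One caveat the structure study
makes explicit: a clone with fitness 0.05 can never exceed a VAF of
about $3 \times 10^{-4}$ under this growth model (fewer than one
expected read at depth 2000), so the "very different fitness" design is
run at that clone's maximum attainable frequency — acquisition at birth —
where the slow clone remains near the detection floor by construction.

## A worked example

```{r example, eval = FALSE}
set.seed(7)
cohort <- simulate_cohort("LBC", 30)
filt <- apply_variant_filters(cohort$variants)
participants <- build_trajectories(filt$kept, covariates = cohort$covariates)
fits <- ch_fit_cohort(participants)
summary(fits[[1]])
metrics <- cohort_metrics(participants, fits)
cmp <- compare_isolated_vs_context(fits, t = 120)
cmp$summary
cox <- fit_cox(metrics, cohort$covariates[, c("participant_id",
                                             "followup_years", "event")])
cox$results
```

## Known limitations

Fitness is assumed constant over a clone's whole history; the wild-type
pool size is fixed rather than inferred, so reported ATMA inherits any
miscalibration of $N$; structure inference treats clones independently
during fitting (see above); the binomial emission has no overdispersion
term, which understates uncertainty if library preparation adds
extra-binomial noise; and associations are correlational — nothing in the
survival or marker stages identifies a causal direction.
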