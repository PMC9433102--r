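---
title: "Models and methods behind tcrlong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrlong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrlong)
```

`tcrlong` analyzes longitudinal UMI-tagged TCRα/TCRβ repertoire sequencing
of sorted T cell subsets: reads in, clonotype tables, richness and
clonality estimates, paired-αβ projections, overlap and publicity
statistics, and percent-per-year age slopes out. This vignette explains
the models and the choices behind them; it states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## From reads to clonotypes

Reads are laid out `[sample barcode][12-bp UMI][V tag][CDR3][J tag]`. One
UMI marks one mRNA molecule, so counting distinct UMIs counts molecules
rather than PCR duplicates. The pipeline:

1. **Demultiplexing** assigns reads to samples by exact barcode prefix
   match; unknown barcodes go to `undetermined` and are counted.
2. **UMI quality filter**: reads whose mean Phred over the 12 UMI bases is
   below 10 are discarded. The threshold is interpreted as a mean over the
   UMI region, the natural reading of a per-UMI quality score.
3. **Consensus**: within a UMI, reads are clustered by sequence identity —
   identical length and at most 1 mismatch merges into the nearest
   existing cluster, visited in order of decreasing read count then
   lexicographically, so the result is deterministic for a fixed input
   multiset. Each cluster with ≥ 3 supporting reads emits one consensus by
   position-wise majority vote (ties broken alphabetically). Clustering
   rather than discarding handles genuinely conflicting TCR sequences
   under one UMI (UMI collisions or contamination): each sufficiently
   supported variant survives as its own record. The 1-mismatch merge
   radius matches the sub-1% per-base error regime the generator emulates.
4. **Annotation** matches the leading/trailing 20-nt tag regions against
   the V/J reference with a tolerance of 2 mismatches. Tags in the
   bundled reference are kept at pairwise Hamming distance ≥ 6, so a
   2-mismatch tolerance can never produce an ambiguous call. The CDR3
   junction between the anchors is translated; records with no V or J
   match, inconsistent chain calls, or out-of-frame junctions are dropped
   and counted.
5. **Functional filter**: CDR3s containing stop codons are removed, and
   records need ≥ 3 supporting reads.
6. **Collapse**: one row per clonotype with `duplicate_count` = number of
   distinct supporting UMIs. Two keys are supported throughout:
   V + J + CDR3aa for diversity analyses, and
   V + CDR3aa + CDR3nt + J for overlap and contamination analyses, where
   nucleotide identity matters.

On error-free reads with every UMI at ≥ 3 reads this chain is exact: the
recovered table equals the generator's truth table, which the test suite
asserts clonotype-by-clonotype.

## Contamination removal

A specific (UMI, TCR nucleotide sequence) pair recurring in two samples is
far more likely carried-over material than coincidence: with typical
per-sample diversities of ~10⁶ UMIs and ~10⁴ TCR sequences, an
independent recurrence has probability ~10⁻¹⁰
(`collision_probability()`). Collisions are therefore resolved by PCR
amplification time: the earliest-amplified record is the presumptive
source and is kept; if several samples tie at the earliest time the
evidence is uninformative and every record in the group is removed — note
this removes later records too, since their provenance is equally
unresolvable. `pcr_time` is an ordinal label; integer batch indices and
ISO timestamps both sort correctly. Collisions are keyed on the
nucleotide-level clonotype because contamination is physical molecules;
an amino-acid key would over-remove convergent clones. The operation is
idempotent, and records whose pair occurs in a single sample are never
touched.

## Cell accounting

Richness is projected to the number of cells a donor actually carries:
`lymphocytes/µL × subset fraction × blood volume`. Blood volume comes from
Nadler's anthropometric formula (male `0.3669·h³ + 0.03219·w + 0.6041` L,
female `0.3561·h³ + 0.03308·w + 0.1833` L, h in meters, w in kg). Height
is in meters internally; centimeters must be requested explicitly
(`units = "cm"`) because the cubic term makes silent unit mixups the
dominant failure mode. Projection targets are 1/100 of the circulating
population by default, keeping the extrapolation within a numerically
sensible range; rounding is half-even and applied only at this final step.

## Richness extrapolation

The estimator extrapolates a rarefaction curve. `rarefy()` computes, by
Monte Carlo, the mean number of unique clonotypes in random
without-replacement subsamples of the UMI pool at each size (the mean
converges to the exact hypergeometric expectation; the test suite checks
agreement with `vegan::rarefy`). Two curves are built: one spanning the
full (optionally depth-normalized) UMI count and one spanning half of it.
When samples are compared, a common depth — the minimum total UMI count
across the comparison set — should be passed as `normalized_depth`.

Eight saturating forms are fitted to the full curve by nonlinear least
squares (`minpack.lm`): Michaelis–Menten, power, logarithmic, negative
exponential, scaled Weibull CDF, rational 2/1 (quadratic over linear),
Gompertz, and shifted logistic. The registry is a plain list and can be
extended. Each model's score is

```
100 × (MAPE of the full-curve fit
       + MAPE of the half-curve fit's predictions beyond the half depth)
+ 1000 per violated plausibility criterion
```

The plausibility criteria require the fitted curve, out to the target, to
be non-decreasing, to decelerate, and to predict at least the observed
unique count. The half-curve term measures extrapolation skill directly:
a model is trusted at 2× extrapolation before being asked to extrapolate
further. Scores above 250 are excluded; among the rest the 3 lowest-score
models are used, extended to at most 5 while scores stay within 10% of
the best, and their predictions at the target population are combined by
geometric mean. The cutoff of 250 is retained for interface fidelity, but
because this score is this package's own construction its absolute scale
is a convention; the estimates, not the scores, are the comparable
quantity. When no model passes, the result is an explicit failure object,
never a silent number.

Under the generator's default conditions — 5000 clones with log-normal
(σ = 1.5) sizes, sampled without replacement at 10% of the population —
the suite requires the median estimate over 20 seeds to fall within ±30%
of truth. The ensemble is conservative in this regime (bounded models
pull the geometric mean below the truth), which is consistent with
treating extrapolated richness as a lower-bound-flavored estimate; at
higher sampling depths the bias shrinks.

## Inverse Simpson's Index

`ISI = 1/λ`, `λ = Σ pᵢ²`, with `pᵢ` the UMI share of clonotype *i*. ISI
equals the clone count under perfect evenness, falls as mass concentrates
(clonal expansion), and is bounded by `[1, #clones]`. These invariants,
permutation invariance, and a majorization check are all asserted on
small cases.

## Paired αβ richness

Bulk sequencing measures the two chains separately. On single-cell paired
data the number of distinct αβ pairs is linear in the chain richness
values once the larger chain count is subtracted:

```
paired − max(f·α, β) = M · (f·α + β),  intercept fixed at 0
```

`f` is the single-TCRα fraction — dual-TCRα cells inflate bulk α counts,
so α is multiplied by `f` in both the sum and the max term. The
through-origin slope has the closed form `M = Σxy / Σx²`. Construction
guarantees `paired ≥ max(f·α, β)` and degree-1 homogeneity, both verified
on 10⁴ random inputs. Shipped lineage constants (CD4: M = 0.138,
f = 0.870; CD8: M = 0.035, f = 0.846) are available as
`pairing_model_cd4()`/`pairing_model_cd8()`; fitting your own single-cell
summaries via `fit_pairing_model()` marks provenance `"fitted"`. Samples
under 2000 cells are merged by greedy accumulation in input order before
fitting (`merge_small_samples()`) so sample sizes resemble bulk samples;
the grouping rule is a package choice, as is fitting without outlier
removal. The cohort generator's "true" paired richness is, by convention,
the published lineage equation applied to the true chain richness.

## Overlap, publicity, abundance

Unique-sequence overlap uses set identity on the nucleotide-level key.
Two standard symmetric forms are implemented — Jaccard
`100·|A∩B|/|A∪B|` (default) and Sørensen `100·2|A∩B|/(|A|+|B|)` — and the
variant used is recorded as an attribute on every result, never silently
assumed. Total-sequence overlap weighs shared clonotypes by UMI mass; the
default two-sided reading `100·(UMI_A(shared)+UMI_B(shared))/(UMI_A+UMI_B)`
gives the natural A = B → 100% identity, and a one-sided reading is
available. Publicity pools all of a donor's samples and visits: a TCR
(amino-acid key) found in exactly one donor is private, otherwise public,
with publicity = number of donors. Abundance profiles take each TCR's UMI
percentage within each donor, the median across donors carrying it, and
summarize per publicity level on a log10 scale.

## Longitudinal inference

Responses spanning decades (richness, cell counts) are modeled on the
log10 scale: `log10(y) ~ age + sex + (1 | donor)` via `nlme::lme`, i.e. a
random intercept per donor and no age × sex interaction. The age slope
`S_old` (log10 units/year) converts exactly to percent change per year,
`S_new = (10^S_old − 1)×100`, with `percent_to_slope()` as the inverse.
P-values are Wald tests on the age coefficient; 0.05 is the declared
significance threshold. On degenerate inputs (e.g. noise-free responses,
where the mixed fit is singular) the function falls back to ordinary
least squares with a warning rather than failing.

Technical variation is estimated from replicate aliquots sequenced
independently: `replicate_sd()` takes the sample SD of log10 richness per
cell type. A donor's change between visits is called only when it exceeds
one replicate SD *strictly* — a change of exactly 1 SD is `no_change`.
Both the SD and the classification operate on the log10 scale by default,
consistent with the log10 slope analysis; a raw-scale option exists
because the choice of scale for the 1-SD rule is genuinely open.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions the rest of the package is validated under:

- **Cohort design**: 30 donors, half male and half female, first-visit
  ages 28–76, two visits separated by a gap drawn from a Beta law
  rescaled to 7–13 years with mean 9.
- **Richness trajectories**:
  `log10 R(age) = log10(baseline) + S_old·(age − 50) + b_donor + ε`, with
  donor intercepts `b ~ N(0, 0.3²)` log10 units and residuals
  `ε ~ N(0, 0.1²)` — spreads chosen so simulated cohorts span roughly two
  decades of richness, the scale of variation seen across healthy adults.
  Default generative slopes are the reported naive-subset declines
  (CD4 α −0.66, CD4 β −2.27, CD8 α −2.19, CD8 β −3.48 %/year) with
  memory subsets flat, since no significant memory richness decline is
  reported. With zero noise the construction reduces to exact compounding:
  `R₂ = R₁·(1 + pct/100)^gap`, which the tests exploit as a closed-form
  oracle.
- **Clone structure**: clone cell counts are log-normal (σ = 1.5) by
  default — the heavy tail mimics clonal expansion — with a power law as
  the alternative; the empirical clone-size law of real repertoires is
  not known precisely, so this is a declared assumption, not a fact.
  Clone frequencies sum to 1 exactly; a visit-1 clone persists to visit 2
  with probability 0.5 (retained clones are a subset of both visits'
  universes). Baseline richness defaults to 2000 clones per
  donor/subset/chain — desk scale, far below real repertoires, chosen so
  full test cohorts simulate in seconds.
- **Reads**: ~30 reads per UMI (1 + Poisson, or exactly fixed), constant
  Phred 30, per-base substitution errors at a configurable rate applied
  across the whole read, and a truth sidecar mapping every UMI to its
  clonotype.
- **Sequences**: V/J calls come from a bundled 20 V × 10 J per-chain
  synthetic reference with well-separated 20-nt tags; CDR3s are random
  in-frame codon stretches with canonical Cys/Phe anchors, unique per
  (V, J, junction) within a donor's universe, and deterministic given the
  cohort seed (regenerable lazily per subset/chain). A configurable
  fraction carries internal stop codons to exercise the functional
  filter.
- **Single cells**: every cell has one β and one or two distinct α
  chains; the dual-α probability defaults to 0.13, matching a
  single-TCRα fraction of 0.87.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no V(D)J recombination statistics or biased
gene usage, no thymic selection or HLA restriction, no indels or
PCR-chimera artifacts, clone identity is independent of sequence content,
and richness is orders of magnitude below in vivo values. The tests
demonstrate algorithmic correctness and statistical calibration under a
controlled generative model, not biological fidelity.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately small instances: cohorts of
2–30 donors, per-subset richness 30–2000, richness-recovery populations
of 5000 clones at 10% sampling with 50 rarefaction resamples and ~300
curve points, slope recovery over 20 replicate cohorts, and read-level
checks on tens of clonotypes at 3–4 reads/UMI. Defaults in the API are
larger (1000 resamples, rarefaction length 2000) and match routine use.
Other fixed choices: curve fitting rescales subsample sizes by the
deepest point for conditioning; model non-convergence drops the model
with a message; monotonicity/deceleration are checked on a 201-point grid
out to the target with a 10⁻⁶ relative tolerance; the seed of every
stochastic step is explicit, and a fixed seed reproduces tables and FASTQ
output byte-for-byte.

## Known limitations

- The richness ensemble is conservative at low sampling depth; its
  estimates should be read as lower-bound-flavored.
- The consensus step is substitution-only (no indel-aware alignment), in
  keeping with the generator's error model.
- The mixed model assumes a linear age trend on the log10 scale; no
  nonlinear age effects, interactions, or multiple-testing correction
  across responses are provided.
- Publicity is sensitive to sequencing depth: shallow samples understate
  sharing, and no depth correction is applied.
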