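---
title: "Models and methods behind ohia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ohia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ohia` implements the population-genomic toolkit for studying an
incipient radiation of a long-lived woody plant whose continuous forest
stands resolve into three genetic clusters (labelled G, I and P after
the glaberrima-, incana- and polymorpha-type varieties of the Hawaiian
ʻōhiʻa system): windowed diversity and differentiation statistics, a
four-method selection scan with an integration layer, and demographic
model comparison on the joint three-population site-frequency spectrum
(SFS). Because no processed genotype data of that kind are freely
reusable, the package carries its own structured-coalescent generator,
and every statistical claim the package makes about itself is exercised
on that generator's output.

## The structured-coalescent generator

The generator (`demography_config()`, `sample_config()`,
`generate_dataset()`) simulates a three-deme structured coalescent with
two population splits at `T1 >= T2` generations before present, an
internal-branch size `NB` between the splits, a root size `NA_`, and two
migration epochs separated by a change point `TC <= T2`: rates
`m01, m02, m12` younger than `TC` and `k01, k02, k12` older; `m3` acts
between the two lineages alive in `[T2, T1)`. Events are drawn by a
continuous-time exponential race (Gillespie), which is exact for the
structured coalescent and faster than generation-by-generation
simulation. Epoch boundaries are processed idempotently at the top of
each event step so that floating-point drift around a boundary can
never strand a lineage in a retired deme.

Loci are independent genealogies (free recombination between loci, none
within). Intra-locus recombination is approximated, when requested, by
cutting a locus into `n_segments` equal-length independent genealogies;
ancestral-recombination-graph simulation is out of scope, so a literal
per-bp recombination rate is not offered. For haplotype-based scans
this segment approximation supplies the essential feature — decay of
haplotype identity with distance — without an ARG.

Hard sweeps are injected deterministically: inside the tract every
haplotype of the target deme is replaced by a chosen carrier, then
"residual" singleton mutations are added at new positions (expected
count = `singleton_rate` x the pre-sweep tract SNP count per target
haplotype, default 0.005 — a just-completed sweep carries few new
mutations), emulating mutation accumulation since fixation. Replacement rather than forward simulation gives an exact
ground-truth tract for detection experiments.

### Default parameter values

Split times, the migration change point, the mutation rate
(7e-9 per site per generation) and the sample sizes (14/14/12 diploids)
are the study conditions themselves. Present and ancestral sizes and
the two migration-rate levels are not published as numbers, so they
were calibrated once so that the generator reproduces the radiation's
stated diversity regime — within-cluster nucleotide diversity near
0.005, genome-wide pairwise Weir–Cockerham FST near 0.10, negatively
skewed windowed Tajima's D — while keeping the population migration
rates inside the published ranges (recent 2Nm = 10, ancient 2Nk = 0.25,
a 40-fold change). The chosen defaults are `N0 = 250000`,
`N1 = N2 = 180000`, `NA_ = 120000`, `NB = 180000`, `m = 2e-5`,
`k = m3 = 5e-7`. They were frozen before the acceptance experiments
were written and are not revisited.

What the generator does *not* emulate: sequencing error and depth
variation (no depth-based genotype masking is needed or modelled),
reference bias, variable mutation/recombination maps, linked selection
outside the injected tracts, and genuine ARG linkage. Passing tests
therefore demonstrate correctness of the statistics and the designed
detection behaviour under idealized data, not robustness to the
artefacts of real resequencing pipelines.

## Windowed statistics

All windows are 0-based half-open 20-kb tiles anchored at 0 (VCF I/O is
1-based). π and DXY use missing-data-aware ratio-of-sums estimators:
per site, π counts `a(n-a)` mismatching pairs over `n(n-1)/2`
comparable pairs, DXY counts cross-population mismatches over `n1·n2`
pairs; monomorphic genotyped positions enter only the denominator. In
the synthetic setting every unrecorded position is a fully genotyped
invariant site (`invariant = "complete"`); with real all-sites input the
`"none"` convention restricts to recorded positions. Windows with empty
denominators are missing, never zero.

Tajima's D uses the standard 1989 constants; sites contribute with
their own non-missing allele count and the constants use the
window-modal count (the upstream tool the study used does not document
its missing-data rule, so this one is ours). Weir–Cockerham FST sums
the a, b, c variance components over eligible SNPs (minor allele count
at least 4 within the pair) and clamps negative or undefined window
values to 0; windows with fewer than 20 eligible SNPs are flagged
ineligible. Runs of homozygosity terminate at heterozygous calls,
tolerate interior missing calls, and report 1-based inclusive spans
with no minimum SNP count. LD decay is the squared Pearson correlation
of dosages over complete cases, binned to 100 kb.

## The selection scan and its integration

*xp-EHH.* Site-EHH at marker x is the probability that two random
haplotypes are identical from the core through x (alleles pooled at
the core); iES is its trapezoidal integral outward in both directions,
truncated where the profile drops below 0.05. The cross-population
score is `ln(iES_A/iES_B)`, standardized genome-wide, with two-sided
normal p-values and outliers at p < 1e-6 (the threshold choice of
sidedness is not documented upstream; two-sided is used). EHH regions
around outlier SNPs extend while the focal profile stays above the
truncation threshold; overlapping or adjacent regions merge (merge gap
0), and only regions supported against both other clusters survive.

*Composite sweep statistic.* Over sliding stretches of 50 clean SNPs
(complete and polymorphic within the population), the statistic is the
product of a density factor (observed span over expected span), an SFS
factor (fraction of minor-allele singletons) and an LD factor
(within-half over cross-half mean r², halves of 25 SNPs, cross floor
0.01). These factor formulas are this package's reconstruction of the
published description ("polymorphism, LD, SFS-change"); bit-level
equivalence with the original sweep scanner is a non-goal. Stretches
overlapping long (>1 kb) no-record gaps, or covered >20% by 100–1000-bp
gaps, are excluded; outliers exceed the valid-stretch mean + 20 sd.

*kNN FST-vector outliers.* Each eligible window is a 3-vector of
pairwise FST. The outlier score is the rank-weighted (linearly
decaying) sum of distances to the k nearest windows; ΔFST is the
distance to the medoid. Outliers need a top-0.5% score *and*
ΔFST > 0.5. The published weight function is not recoverable; linear
rank decay is used with an unweighted option. When the published
k = 6993 exceeds the window count, k rescales to ⌈0.35 N⌉, preserving
the implied k/N ratio.

*Tails and integration.* π and Tajima's D flag their bottom 5%, DXY its
top 5% (inclusive ties; missing windows excluded from the quantile).
Region enrichment uses one-sided Fisher exact tests, and the
integrated report retains an EHH region only with at least one
corroborating signal — the "evidence from other methodologies" rule.
The antagonistic-pleiotropy screen flags FST-outlier windows where
strictly more than half of eligible SNPs differ in allele frequency by
more than 0.95.

## Structure and landscape genomics

PCA centers dosages per SNP without variance scaling by default
(scaling is an option; the study does not state it). dbMEM builds
haversine great-circle distances (radius 6371 km), truncates at the
longest minimum-spanning-tree edge (distances beyond it become four
times the truncation), Gower-centers −0.5 d², and keeps
positive-eigenvalue eigenvectors. RDA is ordinary least squares of the
(covariate-residualized) response on predictors; adjusted R² is
Ezekiel's formula with the predictor rank. Permutation tests permute
rows of the reduced-model residuals (the standard choice for partial
models, unstated in the study) with p = (1 + #{F* ≥ F})/(1 + n). The
implementation is deliberately independent of `vegan`; the test suite
uses `vegan::rda`, `RsquareAdj` and `varpart` as the external
cross-check. Forward selection admits the best candidate only when its
conditional permutation p < 0.05 and the cumulative adjusted R² does
not exceed the all-variable model's.

## Demographic inference

The observed folded 3D SFS indexes minor-allele counts per cluster,
with exact 50% sites resolved to the lexicographically smaller of a
configuration and its complement. The expected SFS accumulates branch
lengths by descendant configuration over simulated genealogies (2000
per evaluation at desk scale), folds, and normalizes; it also records
the per-site polymorphism probability `p_poly = 1 − exp(−E[L] μ)`.

The composite likelihood multiplies the polymorphic-conditional terms
by `p_poly` and adds `M·log10(1 − p_poly)` for the monomorphic tally
whenever one is available. This departs from a purely
polymorphic-conditional likelihood on purpose: a normalized folded SFS
is exactly invariant to rescaling all sizes and times by a constant
(with migration rates inversely scaled), so without the monomorphic
anchor the absolute parameter scale is unidentifiable and no
parameter-recovery experiment can succeed. The monomorphic term plays
the same role the 500,000-site survey (of which only ~7% were SNPs)
played in the original analysis.

The 24-model family crosses two timing hypotheses (recent: T2 < 15,000
generations, constant migration, 11 free parameters; old: T2 > 15,000
with a rate change at TC < 15,000, 15 parameters), two topology shapes
(nested/radiating) and the six cluster-to-deme assignments, cycling
assignments within blocks as in the published comparison table.
Search ranges: sizes 1e2–1e6, T1 100–5e5, migration 1e-8–1e-2,
log-uniform starts.

Fitting is cyclic coordinate search on the log scale with common
random numbers per run (the objective is deterministic within a run):
run 1 starts from a moment-based point (per-deme diversity → sizes via
π = 4Nμ; pairwise divergence minus mean diversity → split times via
dxy = π_anc + 2Tμ), later runs start log-uniformly at random; the
first cycle scans each parameter over its whole range, later cycles
refine in shrinking multiplicative windows, and each cycle ends with a
coalescent-scale move (sizes and times jointly, migration inverted) —
the sloppy direction of SFS models that single-coordinate moves cannot
follow. AIC converts the log10 composite likelihood with the natural-log
factor, `AIC = 2k − 2 ln(10) log10 L`, the only convention that
reproduces the published comparison table's arithmetic.

Parametric bootstrap intervals rescatter the fitted model
(site-level binomial/multinomial draws), refit each replicate with the
same moment-started estimator, and report *basic* (reflected)
intervals on the log scale — `exp(2 log θ̂ − log q)` — rather than raw
percentiles, because refits inherit the estimator's first-order bias
and reflection cancels it; raw percentiles remain available.

## Validation experiments and problem sizes

The packaged experiments (also run by `scripts/acceptance.R`) use
desk-scale problem sizes chosen to keep a complete run modest on one
core while leaving each check statistically meaningful:

- Sweep-recovery datasets: 10 loci × 100 kb × ten 10-kb segments (50
  windows of 20 kb), 20 seeds, one 40-kb tract (30–70 kb of locus 1,
  matching the 49–176-kb scale of the regions the radiation's published
  scan reports); sized so the tract stays a small fraction of scored
  SNPs and does not inflate the xp-EHH standardization. Neutral
  calibration uses 20 seeds of a smaller 6-locus version of the same
  configuration.
- Neutral Tajima's D: 20 seeds × 15 single-genealogy 20-kb loci of a
  constant-size panmictic population (≥ 200 windows pooled).
- Coalescent analytic check: 10,000 genealogies at n = 4 against the
  harmonic 1/i closed form.
- Demographic recovery: 10 trials at 6/6/6 haploids, 2,000 simulations
  per likelihood evaluation, 500,000 surveyed sites, 8 bootstrap
  refits per trial; discrimination against a rotated-assignment model
  on the same data. At this scale the folded spectrum retains little
  topology polarity and leaves long likelihood ridges, so bootstrap
  coverage and assignment discrimination are the two checks most
  sensitive to it (see Known limitations).
- Permutation calibration: 100 pure-noise RDA datasets at 199
  permutations.

## Known limitations

- The composite likelihood ignores linkage between sites (as composite
  likelihoods do); bootstrap intervals inherit this.
- The coordinate search is a local optimizer with a global first sweep;
  at desk scale some likelihood ridges (notably T1 against the
  ancestral sizes and migration) are traversed slowly and fits can
  stall a few log-likelihood units short of the optimum. Because the
  folded small-sample spectrum separates rival cluster-to-deme
  assignments by only a few log-likelihood units, model discrimination
  and bootstrap-interval coverage are the least robust of the packaged
  experiments at desk scale.
- The μ-statistic factors and the kNN weight function are documented
  reconstructions, not re-implementations of the original tools.
- ROH calling is rule-based (no HMM), LD uses genotype dosages (no
  haplotype EM), and phasing is assumed given (synthetic truth or
  phased input), all per scope.
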