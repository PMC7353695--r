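---
title: "Demographic inference from RAD-seq SNPs with coalABC"
author: "coalABC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference from RAD-seq SNPs with coalABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalABC)
```

## The scientific problem

Tropical montane birds are expected to have *expanded* during Pleistocene
glacials: global cooling shifts vegetation belts downslope, enlarging the
area of montane forest and sometimes reconnecting populations stranded on
neighbouring ranges. A genomic test of this hypothesis asks whether the
site-frequency spectrum and diversity of a present-day population carry the
signature of a recent expansion, when that expansion happened, and whether
its timing matches a glacial onset rather than a warm interglacial.

`coalABC` implements the full inferential pipeline this question needs for
reduced-representation (ddRAD-style) SNP data from a single population:

1. a coalescent simulator for unlinked biallelic SNPs and short sequence
   loci under piecewise-constant effective population size;
2. DIYABC-style approximate Bayesian computation (ABC): rejection plus
   weighted multinomial logistic regression for model choice, and
   local-linear (Beaumont-style) regression adjustment for parameter
   estimation;
3. validation machinery: posterior-predictive checks, pseudo-observed-data
   error rates, bias/precision estimates, and a power analysis over SNP
   counts;
4. the descriptive population-genomic statistics such studies report
   (observed heterozygosity, effective number of alleles, PIC, nucleotide
   diversity, Tajima's D, Weir–Cockerham F~ST~ with permutation tests,
   Dxy, Nei's D, net p-distance) and structure diagnostics (PCoA,
   individual-based Mantel test, Evanno ΔK, mutual k-nearest-neighbour
   graphs).

## The three demographic models

All three models describe a single panmictic diploid population observed
today; time `t` runs backwards in generations.

* **constant** — effective size `Nc` at all times;
* **lgm** — a step expansion at the onset of the last glaciation:
  size `Npost` for `t < Texp`, ancestral size `Nanc` for `t >= Texp`, with
  `Texp` constrained a priori to 10,000–40,000 generations BP;
* **interglacial** — the same step history with `Texp` constrained to the
  last interglacial, 110,000–130,000 generations BP.

A generation time of one year (typical for small passerines) makes
generations and years interchangeable. The default priors are uniform:
`Nc ~ U(100, 200000)`, `Nanc ~ U(100, 30000)`, `Npost ~ U(10000, 200000)`,
and the `Texp` windows above. They are wide enough to bracket any plausible
posterior for a montane songbird while keeping the two expansion models
distinguishable chiefly by timing; all are overridable via the `priors`
argument.

## The coalescent simulator

While `j` lineages remain, the waiting time to the next coalescence has
hazard `choose(j,2) / (2 Ne(t))`; event times under a step history are
obtained by piecewise rescaling of unit exponentials (never by rejection).
`simulateTree()` returns an `ape` `"phylo"` genealogy, and
`simulateSequenceLocus()` drops Poisson-distributed infinite-sites
mutations on it for the sequence-based statistics.

SNP loci need care. A RAD-seq SNP matrix contains only loci observed to be
*variable in the sample*, so the simulator must condition on polymorphism.
In the small-mutation-rate limit this conditioning tilts the genealogy
measure by total branch length `L`, and the marginal distribution of a
SNP's derived-allele count becomes exactly

&nbsp;&nbsp;`P(count = i) = E[l_i] / E[L]`,

where `l_i` is the length of branches subtending `i` tips — the classical
`1/i` neutral law under constant size. `simulateSnpCounts()` samples this
distribution exactly and cheaply: the "level" `j` (number of ancestral
lineages present when the mutation occurs) is drawn with probability
proportional to `j E[T_j]`, and the subtended tip count given the level
follows Fu's (1995) exchangeable-topology distribution
`P(i | j) = C(n-i-1, j-2) / C(n-1, j-1)`. The expected level durations
`E[T_j]` under a two-epoch history are computed in closed form by a stable
recursion on the Laplace functionals of the level start times in
coalescent-scaled time (where level durations are independent
exponentials). Because topology is independent of branch lengths, the
length tilt leaves Fu's distribution untouched, and by tip exchangeability
the carriers of a mutation are a uniform random subset of lineages given
the count. The test suite checks this fast path against the explicit
(length-weighted) tree route and against the analytic `1/i` spectrum.

One consequence worth knowing: placing a single mutation on an
*unconditioned* tree proportionally to branch length (the classic fixed-S
device) is *not* the same distribution — it over-produces singletons by a
few percent. `simulateSnpLocus()` retains the fixed-S semantics for a
user-supplied genealogy; dataset and reference-table simulation use the
conditioned sampler.

`simulateDataset()` pairs consecutive haploid lineages into diploids
(random mating, no inbreeding parameter), injects per-genotype missingness
uniformly at random (the missingness mechanism of real RAD data is not
modelled — only its rate), and records the truth scenario for recovery
tests.

## The ABC engine

`buildReferenceTable()` draws parameters from the priors and simulates,
for each draw, the same four single-population summary statistics that are
computed on observed data by `abcStats()`:

* proportion of monomorphic loci (among non-missing calls),
* mean per-locus unbiased gene diversity `2n/(2n-1) (1 - p² - q²)`,
* the sample variance of per-locus gene diversity,
* mean minor-allele frequency.

This set follows the standard single-population SNP statistics of
DIYABC-style analyses; the statistic routine is deliberately shared
between observed and simulated data (a symmetry the tests enforce).
Because simulated loci are polymorphic by construction, the
monomorphic-proportion statistic has zero variance in the reference table
and is dropped from distance computations (with a message) — it
participates only when observed data with missingness make it
informative.

`abcReject()` standardises each statistic by its reference-table standard
deviation and accepts the `nAccept` Euclidean-closest rows (ties broken by
row index). `modelChoice()` reports both the rejection estimate (model
frequencies among the accepted) and a weighted multinomial logistic
regression (Epanechnikov weights in distance, fitted with
`nnet::multinom`, evaluated at the observed point), falling back to
rejection — flagged — when a model has fewer than two accepted rows or the
fit fails.

`estimateParams()` implements the local-linear adjustment on the logit
scale defined by each parameter's prior bounds: transformed parameters are
regressed (weighted) on statistic deviations and translated to the
observed point, so adjusted draws always respect the prior support.
Quantiles are weighted (5/50/95%). A singular design falls back to the
unadjusted rejection posterior, flagged. Calibration is tested on a
conjugate toy problem (uniform prior, Gaussian likelihood, sample-mean
statistic) against the analytic truncated-normal posterior, and by
probability-integral-transform uniformity of posterior-predictive
percentiles.

Validation mirrors standard practice: `ppcCheck()` reports the percentile
of each observed statistic in the posterior-predictive cloud ("within the
posterior space" = all percentiles in (0.5, 99.5)); `posteriorErrorRate()`
samples model/parameter pairs from the accepted set, simulates a fresh
pseudo-observed dataset from each (the sampled row itself is excluded from
the reference when scoring) and reports how often the true model fails to
win; `biasPrecision()` re-estimates parameters on datasets simulated from
the posterior and reports mean relative bias and relative RMSE.

## Problem sizes and what the defaults mean

The motivating analyses used one million simulations per model. The
package's defaults are scaled for interactive use: reference tables of
10,000–50,000 rows per model reproduce every qualitative result (and, at
50,000/model, the exact model-choice outcomes: posterior probability 1.0
for the true expansion model and a pseudo-observed error rate of 0); the
test suite and the acceptance script use 50,000 per model for the
recovery and error-rate checks and 10,000 per model inside the power
analysis, sizes chosen so a full run stays in the tens of seconds on one
core. `nAccept = 500` follows the source analyses; as a fraction of the
table it is more permissive at desk scale than at 10⁶ rows, which widens
posteriors slightly but does not move their centres.

The power analysis (`runPower()`) re-creates the published simulation
design: truth `Nanc = 10^4 -> Npost = 10^5` at `Texp = 28,000`
generations, 20 diploid individuals, SNP counts 500/1000/2000/3000 with
five replicate observed datasets per count. One reference table is built
per SNP count (summary statistics depend on the locus count) and is shared
across the replicates of that count, as is statistically proper — the
table is independent of the observed data. Posterior medians are recorded
under the truth-kind model so replicates aggregate; misidentifications are
counted separately. With these defaults the recovered expansion time sits
a few thousand generations *above* the truth (posterior medians ~30,000–32,000
for a 28,000 truth) — the same mild upward bias the original DIYABC-based
analyses report — and the across-replicate SD of the medians decreases
with SNP count (Spearman ρ < 0 for `Texp` and `Npost`).

## Numerical and convention choices

* **F~ST~** — "distance-method" AMOVA F~ST~ is replaced by the
  field-standard Weir–Cockerham (1984) θ (ratio of sums of the a/b/c
  components across loci), numerically close for biallelic SNPs; the
  10,000-permutation test is preserved exactly, with
  `p = (#{θ* ≥ θ} + 1)/(nPerm + 1)`. Loci with fewer than two non-missing
  genotypes in either group are dropped pairwise.
* **Gene diversity** uses the unbiased factor `2n/(2n-1)`; observed
  heterozygosity is the raw heterozygote fraction. Under random pairing
  `E[Ho]` equals the *unbiased* gene diversity, a `2n/(2n-1)` subtlety the
  Hardy–Weinberg calibration tests respect.
* **Net p-distance** uses plug-in within-group diversity (ordered pairs,
  self-pairs included), so a group compared with an identical copy of
  itself gives exactly zero; for diverged groups the difference from the
  distinct-pairs convention is O(π/n).
* **Mantel test** — "999 bootstraps" in GenAlEx terminology is a
  999-permutation test; implemented as such (one-sided, positive
  association). Geographic distance is great-circle (haversine) from
  lat/lon; no log transform is applied by default since the source
  analyses do not state one.
* **PCoA** wraps classical scaling (`stats::cmdscale`); negative
  eigenvalues are reported but yield no axes, and percent explained is
  relative to the positive-eigenvalue sum.
* **Evanno ΔK** requires ≥ 2 runs per K and ≥ 3 consecutive K; positions
  with zero across-run SD are flagged undefined rather than producing
  infinities. The STRUCTURE MCMC itself is out of scope — ΔK operates on
  supplied log-likelihood tables.
* **Mutual kNN** breaks distance ties by index order (documented,
  deterministic); the community-detection-based choice of k used by
  netview is out of scope, so `k` is a user parameter.
* **Determinism** — every stochastic entry point takes a `seed`; the
  compiled kernels draw from R's RNG stream, so a fixed seed gives
  bit-identical output across platforms.
* **Ties and fallbacks** — acceptance ties break by row index; model
  argmax ties break by model order; singular regressions fall back to
  rejection with a flag rather than failing.

## What the synthetic data do and do not show

The generator emulates the downstream products of a ddRAD pipeline:
20–30 diploids, thousands of unlinked biallelic SNPs (one per RAD locus)
with optional missingness, and 140-bp locus alignments. It does not model
recombination within loci, population structure or migration, selection,
sex linkage, sequencing or genotyping error, or the locus-dropout
mechanism behind real missingness (allele dropout is missingness *not* at
random). Passing tests therefore demonstrate that the inference machinery
recovers truth for data generated under its own model class at realistic
sizes — the standard power-analysis claim — not that any particular
empirical dataset is free of the ascertainment or error processes the
model omits.

## Known limitations

* Single-population histories with one step change; no bottleneck-plus-
  recovery or exponential-growth parameterisations.
* Exactly biallelic loci; multi-allelic sites are rejected at import.
* The logistic model-choice probabilities are asymptotically consistent
  but can be overconfident at very small accepted counts; the rejection
  estimate is always reported alongside.
* Posterior error rates at 20,000 simulations/model retain a few percent
  of cross-model confusion that vanishes by 50,000/model; users scaling
  further down should expect noisier model choice.
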