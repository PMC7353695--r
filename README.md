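# coalABC

Coalescent simulation and approximate Bayesian computation (ABC) for
demographic inference from RAD-seq SNP data.

## Who this is for

Population geneticists asking whether a single population carries the
genomic signature of a recent demographic expansion — for example, a
montane forest bird whose habitat expanded downslope during Pleistocene
glacials — and when that expansion happened. The package provides the
whole desk-side workflow: simulate thousands of unlinked biallelic SNPs
under competing demographic histories, choose among the histories by ABC,
estimate the expansion parameters, and quantify how much the data could
ever have told you (error rates, bias, power versus SNP count). The
descriptive statistics such studies report (Ho, Ae, PIC, π, Tajima's D,
Weir–Cockerham F<sub>ST</sub> with permutation tests, Dxy, Nei's D, net
p-distance) and the structure diagnostics (PCoA, Mantel isolation by
distance, Evanno ΔK, mutual k-nearest-neighbour graphs) are included.

## The model

Three single-population histories, time running backwards in generations:

| model | history | parameters |
|---|---|---|
| `constant` | constant diploid size | `Nc` |
| `lgm` | step expansion at the onset of the last glaciation | `Nanc → Npost` at `Texp ∈ [10^4, 4·10^4]` |
| `interglacial` | step expansion in the last interglacial | `Nanc → Npost` at `Texp ∈ [1.1·10^5, 1.3·10^5]` |

Genealogies follow the n-coalescent with piecewise-constant N<sub>e</sub>
(hazard `choose(j,2)/(2Ne(t))` while `j` lineages remain). SNP loci are
conditioned on being variable in the sample; in the small-mutation-rate
limit the derived-allele count then follows `P(i) = E[l_i]/E[L]` (the
classical 1/i law under constant size), which the simulator samples
exactly via Fu's exchangeable-topology distribution and closed-form
expected level durations — fast enough for reference tables of 10^5+ rows
in seconds.

Inference is DIYABC-style ABC on four summary statistics (proportion of
monomorphic loci, mean and variance of per-locus unbiased gene diversity,
mean minor-allele frequency): rejection of the 500 closest simulations on
sd-standardised Euclidean distance; model choice by accepted-model
frequency and by Epanechnikov-weighted multinomial logistic regression;
parameter estimation by local-linear regression adjustment on the logit
scale of the prior bounds, reported as weighted 5/50/95% quantiles.

## Worked example

Simulate an "observed" dataset under a ten-fold expansion 28,000
generations ago, then infer the history back:

```r
library(coalABC)

truth <- demographicScenario("lgm", Nanc = 1e4, Npost = 1e5, Texp = 28000)
spec  <- sampleSpec(nDiploid = 20, nSnpLoci = 2000)
obs   <- simulateDataset(truth, spec, seed = 1)

snpSummary(obs$genotypes)
#>   nSnps effectiveNumAlleles observedHeterozygosity       pic
#> 1  2000            1.176933                 0.1325 0.1142308

tab <- buildReferenceTable(c("constant", "lgm", "interglacial"), spec,
                           nSimsPerModel = 50000, seed = 2)
fit <- abcFit(tab, g = obs$genotypes, nAccept = 500)

fit$modelChoice
#> ModelChoiceResult (posterior model probabilities)
#>           constant lgm interglacial
#> rejection        0   1            0
#> logistic         0   1            0

fit$posterior
#> ABCPosterior for model 'lgm' (500 accepted draws)
#>          q5 median    q95
#> Nanc   5078  10180  15280
#> Npost 53340 105600 146100
#> Texp  16540  32010  39630
```

Both model-choice methods put probability 1 on the glacial-onset
expansion. The posterior medians recover the truth — ancestral size
10,180 (truth 10,000), post-expansion size 105,600 (truth 100,000) — and
the expansion time (median 32,010 for a truth of 28,000) shows the mild
upward bias that is characteristic of this design. A posterior-predictive
check confirms the observed statistics sit inside the fitted model's
predictive cloud:

```r
ppcCheck(fit$posterior, spec, abcStats(obs$genotypes), nDraws = 500, seed = 3)$percentiles
#> propMono    meanH     varH  meanMAF
#>     50.0     50.8     47.4     50.0
```

Validation and power:

```r
posteriorErrorRate(tab, abcStats(obs$genotypes), nPseudo = 500, seed = 4)$errorRate
# fraction of pseudo-observed datasets assigned to the wrong model (0 here)

rep <- runPower(powerDesign(nSimsPerModel = 10000), seed = 1)
summarizeSdTrend(rep)
# Spearman rho of SD(posterior medians) vs SNP count, per parameter
```

## Package layout

* `R/coalsim.R`, `src/coalsim.cpp` — coalescent simulator (trees, SNP
  counts, sequence loci, full datasets)
* `R/abc.R` — reference tables, rejection, model choice, local-linear
  estimation, posterior-predictive check, error rate, bias/precision
* `R/power.R` — power analysis over SNP counts
* `R/popgen-snp.R`, `R/popgen-seq.R`, `R/fst.R` — summary statistics
* `R/structure.R` — PCoA, Mantel, ΔK, mutual-kNN graphs
* `R/io.R` — VCF/TSV/FASTA/YAML readers and writers, the
  missingness + one-SNP-per-RAD-locus filter
* `vignettes/demographic-inference.Rmd` — the methods vignette: model
  assumptions, priors, numerical choices, limitations
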