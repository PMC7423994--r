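# HomeoExpress

Homeolog-specific and non-additive expression analysis for allopolyploids
from RNA-seq counts.

An allopolyploid carries two parental subgenomes, so every locus has two
duplicated copies (homeologs). Two questions drive comparative
transcriptomics of young polyploids such as *Tragopogon miscellus* and its
diploid parents *T. dubius* and *T. pratensis*:

1. **Homeolog expression bias** — within the polyploid, do the two
   homeologs of a locus contribute equally to its expression, and is any
   bias inherited from the parents (*parental legacy*) or novel?
2. **Non-additive total expression** — is the locus' total expression in
   the polyploid the parental average (*additivity*), equal to exactly one
   parent (*expression level dominance*, ELD), or outside the parental
   range (*transgressive expression*)?

HomeoExpress implements the full count-level pipeline for these questions,
plus a Gamma-Poisson simulator with per-locus ground truth so every stage
has a parameter-recovery test surface.

## The models

**Homeolog proportion.** For locus reads split between the two homeologs,
replicate *i* is modelled as x<sub>A,i</sub> ~ Poisson(λ<sub>i</sub> p),
x<sub>B,i</sub> ~ Poisson(λ<sub>i</sub> (1 − p)), with a Gamma prior on the
replicate intensity λ<sub>i</sub> and

&nbsp;&nbsp;&nbsp;&nbsp;p = θ(1 − q<sub>A</sub>) + (1 − θ) q<sub>B</sub>,

where θ is the true proportion of expression from the A homeolog and
q<sub>A</sub>, q<sub>B</sub> are read misassignment rates estimated from
diploid cross-mapping. Conditioning on the replicate total integrates
λ<sub>i</sub> out exactly (x<sub>A,i</sub> | n<sub>i</sub> ~
Binomial(n<sub>i</sub>, p)); with a Beta(a, b) prior the posterior of θ is
evaluated on a uniform grid and, when q = 0, equals the conjugate
Beta(a + Σx<sub>A</sub>, b + Σx<sub>B</sub>) — a built-in correctness
oracle. A locus is *biased* when the 95% equal-tailed credible interval
excludes θ = 0.5. Loci whose diploid reads cross-map predominantly to the
other parent's reference are screened out first.

**Differential expression.** A self-contained negative-binomial Wald test
(Var = μ + φμ²) with median-of-ratios size factors, per-locus
method-of-moments dispersions shrunk toward a fitted mean-dispersion
trend, BH-adjusted two-sided p-values, and a mid-parent-value contrast
testing μ<sub>M</sub> = (μ<sub>A</sub> + μ<sub>B</sub>)/2 as a linear
combination of group means.

**Classification.** The parental DE call × polyploid bias class maps onto
the fixed nine-category scheme (categories 1–3 parental legacy, 4–5
absence of bias, 6–9 novel bias); the three pairwise DE calls (M vs A,
M vs B, A vs B) map onto no change / additivity / ELD / transgressive,
with chi-square balance tests, Fisher comparison of non-additive
proportions between polyploid forms, and a generic hypergeometric /
length-bias-corrected term-enrichment test.

Ortholog pairs between the parental transcript sets are found by
reciprocal best hit on BLAST outfmt-6 tables, filtered at E ≤ 1e-10,
identity ≥ 80%, alignment length ≥ 200 bp (inclusive bounds), and
intersected with externally supplied single-copy groups.

## Worked example

```r
library(HomeoExpress)

cfg <- simConfig(nLoci = 1000, seed = 42)   # 3 reps/group, ~100 reads/locus
sim <- simulateCounts(cfg)

## homeolog bias with misassignment correction
post <- thetaPosterior(sim$homeolog, qA = 0.02, qB = 0.02)
head(as.data.frame(post), 3)
#>     locus_id total_A total_B theta_mean    ci_low   ci_high bias_class
#> 1 locus00001     825     810  0.5047724 0.4795439 0.5299888   unbiased
#> 2 locus00002      90      82  0.5239464 0.4466931 0.6006781   unbiased
#> 3 locus00003     119     128  0.4811747 0.4168505 0.5457857   unbiased

summarizeCountsTable(c(table(post$bias_class)))
#>      class   n  percent percent_display
#> 1 unbiased 776 78.06841            78.1
#> 2 biased_A 104 10.46278            10.5
#> 3 biased_B 114 11.46881            11.5

biasBalanceTest(104, 114)   # balanced bias in this simulation
#> $statistic 0.4587156   $p.value 0.4982249
```

The unbiased share (78.1%) reflects the generator's default 20% biased
loci minus low-count exclusions; the balance test does not reject because
the simulator draws the biased direction symmetrically.

```r
## total-expression patterns from the three pairwise contrasts
A <- SummarizedExperiment::assay(sim$parentA)
B <- SummarizedExperiment::assay(sim$parentB)
M <- SummarizedExperiment::assay(sim$polyploid)
deAB <- nbTest(qcFilter(cbind(A, B))$counts, 1:3, 4:6, contrast = "A:B")
deMA <- nbTest(qcFilter(cbind(M, A))$counts, 1:3, 4:6, contrast = "M:A")
deMB <- nbTest(qcFilter(cbind(M, B))$counts, 1:3, 4:6, contrast = "M:B")
pat <- classifyPattern(deMA, deMB, deAB)
summarizePatterns(pat)$table
#>              pattern   n percent
#> 1          no_change 470    47.0
#> 2         additivity  58     5.8
#> 3              eld_A 116    11.6
#> 4              eld_B 126    12.6
#> 5   transgressive_up 103    10.3
#> 6 transgressive_down 106    10.6
#> 7           conflict  21     2.1
```

92.4% of these calls match the simulated ground truth
(`sim$truth$true_pattern`); additivity is hardest because the polyploid
sits only 1.6-fold from the nearer parent. `runPipeline()` chains all
stages (bias screen → posterior → DE incl. MPV → categories → patterns →
crosslink → enrichment) and `writeReport()` serialises the bundle to JSON.

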