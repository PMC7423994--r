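---
title: "Methods: homeolog bias and non-additive expression in allopolyploids"
author: "HomeoExpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homeolog bias and non-additive expression in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HomeoExpress)
```

# Scope

HomeoExpress analyses locus-level RNA-seq counts from an allopolyploid and
its two diploid progenitors. It answers two questions per locus: (i) do
the two parental homeologs contribute equally to the polyploid's
expression of the locus, and how does any bias relate to the parental
contrast (parental legacy vs novel bias)? (ii) is the polyploid's total
expression additive, dominated by one parent, or transgressive? Everything
upstream of a count table — trimming, assembly, read alignment — is out of
scope; the package consumes counts, homeolog-resolved count pairs,
BLAST-style tabular hits, and diploid cross-mapping assignment counts.

# The homeolog proportion model

For one locus in the polyploid, replicate $i$ yields $x_{A,i}$ reads
assigned to the parent-A homeolog and $x_{B,i}$ to the parent-B homeolog.
The hierarchy is

$$x_{A,i} \sim \mathrm{Poisson}(\lambda_i\, p), \qquad
  x_{B,i} \sim \mathrm{Poisson}(\lambda_i (1-p)), \qquad
  \lambda_i \sim \mathrm{Gamma},$$

with the assignment probability
$p = \theta(1-q_A) + (1-\theta)\,q_B$, where $\theta \in (0,1)$ is the
true A-homeolog expression proportion and $q_A, q_B \in [0, 0.5)$ are
read-misassignment rates. Conditioning each replicate on its total
$n_i = x_{A,i} + x_{B,i}$ removes $\lambda_i$ exactly:
$x_{A,i} \mid n_i \sim \mathrm{Binomial}(n_i, p)$. This conditional
formulation is adopted deliberately: the Gamma replicate intensities
integrate out in closed form, the likelihood depends only on the sufficient
statistics $\sum_i x_{A,i}$ and $\sum_i x_{B,i}$, and the $q = 0$ limit is
exactly conjugate — $\theta \mid x \sim
\mathrm{Beta}(a + \sum x_A,\; b + \sum x_B)$ under a
$\mathrm{Beta}(a, b)$ prior — giving an analytic oracle that the grid
implementation is tested against at every node.

**Numerics.** The posterior is evaluated on a uniform grid over $[0, 1]$
(default 2001 nodes, forced odd) and normalised with composite Simpson
weights; the posterior mean uses the same quadrature. Because prior
parameters are $\ge 1$ and counts are non-negative, the density is finite
at the endpoints. Simpson quadrature keeps the $q=0$ agreement with the
Beta density below $10^{-8}$ relative error for realistic counts (measured
$\sim 10^{-12}$), and the default grid agrees with a $10\times$ finer grid
to better than $10^{-4}$ in the posterior mean when $q > 0$. Credible
bounds come from the trapezoid CDF with linear interpolation, accurate to
about $10^{-5}$ — far below the width of any interval at realistic depth.
Equal A/B totals give a posterior mean of exactly 0.5 by grid symmetry.

**Calls.** A locus is `biased_A` when the equal-tailed interval at `level`
(default 0.95) lies above 0.5, `biased_B` below, otherwise `unbiased`.
Loci with fewer than `minTotal` (default 10) reads across replicates are
excluded and logged rather than called: with a flat prior such calls would
be prior-dominated. All-zero loci are likewise excluded with a reason.

**Misassignment.** $q_A = ab/(aa+ab)$ from diploid cross-mapping counts
(and symmetrically $q_B$), with optional $+0.5$ pseudocount smoothing;
the pipeline pools counts over unbiased-mapping loci for a stable global
estimate. A single locus-level $(q_A, q_B)$ pair is used for all
replicates — replicate-specific misassignment is not modelled. Loci whose
cross-mapping fraction exceeds `crossThreshold` (default 0.5, a literal
reading of "predominantly cross-mapped") are dropped from homeolog
inference entirely; loci with fewer than `minReads` (default 10) diploid
reads in either parent are `indeterminate` and also excluded, because the
ratio is too unstable to label.

# The nine-category scheme and cross-form comparison

The parental DE call (`A_higher`, `B_higher`, `no_de`) crossed with the
polyploid bias class gives nine cells: 1–3 parental legacy (no DE &
unbiased; A-higher & A-biased; B-higher & B-biased), 4–5 absence of bias
(parental DE, no polyploid bias), 6–9 novel bias. The group membership of
each cell is fixed by the definitions; the *numbering* of cells 7–9 within
the novel group is a package convention (no-DE/B-biased, A-higher/B-biased,
B-higher/A-biased), since only the grouping — not the order — carries
meaning downstream. Two polyploid forms are compared as a $3\times3$
contingency table over shared loci; the "maternal-specific" list contains
loci biased toward a form's maternal parent in that form and unbiased in
the other, the quantity relevant to cytonuclear-interaction hypotheses.
Direction-switching loci stay in the switch cell and never enter the list.

# Differential expression

A self-contained NB Wald test is used rather than wrapping an existing
GLM package: the pipeline needs only two-group contrasts and one linear
combination, exact numeric agreement with any particular package is not a
goal, and distributional calibration is testable directly.

* **Normalization** is median-of-ratios over loci with positive geometric
  mean, rescaled to geometric mean 1 (so a pure depth change in one
  sample moves only that sample's factor). With no all-positive locus the
  estimator falls back to total-count scaling with a warning.
* **Gene-level QC** removes zero-total loci, loci with mean normalized
  count below `minMeanNorm` (default 1), and — with $\ge 3$ samples —
  loci where one normalized observation exceeds `outlierFold` (default
  10) times the locus' 20%-trimmed mean, floored at 1 so the rule is
  stable near zero.
* **Sample QC** runs PCA and average-linkage clustering on log2
  normalized counts; a sample is flagged when the cluster it first joins
  already contains another group's member — the dendrogram-based rule a
  practitioner applies by eye when dropping a failed replicate.
* **Dispersion** is estimated per locus by method of moments
  ($\hat\varphi = (v - \bar k \overline{1/s})/\bar k^2$, pooled over
  groups) and shrunk toward a robustly fitted parametric trend
  $\varphi(\mu) = a_0 + a_1/\mu$ by a weighted average. The default trend
  weight of 0.8 was set by the calibration requirement the package states
  for itself: on a 5,000-locus null split of a single simulated
  population (3 vs 3), the empirical type-I error at $p < 0.05$ must lie
  in $[0.035, 0.065]$ and the Kolmogorov–Smirnov distance of the p-value
  distribution from uniform below 0.03. Weights from 0.7 to 1.0 satisfy
  both (measured type-I 0.051–0.057); 0.8 keeps a visible per-locus
  contribution for data whose dispersion genuinely varies around the
  trend.
* **Wald statistic** on $\log_2$ group means with delta-method variance
  $\mathrm{Var}(\bar k_g) = \mu \sum_j s_j^{-1}/n_g^2 + \varphi
  \mu^2/n_g$; a zero group mean is floored at half a read in that group's
  library (a degenerate-input guard — the displayed fold change uses a
  $+0.5$ pseudocount on normalized means but the test never does).
* **MPV contrast** tests $\mu_M = (\mu_A+\mu_B)/2$ on the linear
  normalized scale with variance
  $V_M + V_A/4 + V_B/4$, preserving replicate-level variance instead of
  constructing averaged pseudo-samples. It is mildly liberal (measured
  $\approx 0.065$ at nominal 0.05 under the default design) because group
  means enter the variance as plug-ins; this is acceptable for the
  screening role the contrast plays.
* **FDR** is Benjamini–Hochberg (`stats::p.adjust`); direction calls use
  `fdr < alpha` with `alpha = 0.05`.

A caveat worth stating: median-of-ratios assumes most loci are not
differentially expressed. A hypothetical dataset in which *every* locus
changes by the same factor between groups is indistinguishable from a
depth difference, and any global shift is absorbed into the size factors.
The simulator's default mixture (50% no-change) respects this assumption.

# Pattern classification

The three direction calls (M vs A, M vs B, A vs B) map deterministically
onto seven labels. `no_change` requires the polyploid to differ from
neither parent, regardless of the parental contrast — so a locus with
parental DE but polyploid equivalence to both parents is `no_change`, the
convention under which "no change" shares are reported. ELD requires the
polyploid to match exactly one parent *and* the parents to differ;
additivity requires the polyploid strictly between significantly different
parents with a consistent parental direction. Triples in which the parents
are equivalent but the polyploid differs from exactly one of them — and
between-parent inconsistencies — are labelled `conflict` rather than
coerced into a substantive class: silent coercion would bias the balance
tests, and the conflict rate is reported so users can audit it (about 2%
at default simulation settings). All 27 triples map to exactly one label
(enumerated in the tests), and swapping parent labels exchanges
`eld_A`/`eld_B` while fixing the rest.

# The synthetic-data generator

`simulateCounts()` emulates the study design the package targets: two
diploid parents and one polyploid, three biological replicates each,
log-normal baseline means (meanlog $= \log 100$, sdlog $=1$ — a mean
locus depth near 100 reads with a heavy right tail and enough low-count
loci to exercise the QC filters), Gamma-Poisson counts with dispersion
$\varphi = 0.05$ (typical biological replication), and 2% symmetric read
misassignment applied at the read level through the mixture probability
$p$ — matching the inference model's likelihood, not a post-hoc count
perturbation. Biased loci (20%) draw $\theta$ from $(0.65, 0.90)$ or its
mirror image, so every simulated bias is at least 0.15 from parity.

Each locus receives one of six total-expression patterns
(50% no-change, 10% each of additivity, two ELD directions, two
transgressive directions). The pattern constrains the parental contrast:
a no-change locus must have equal parental means, additivity and ELD
require a parental fold change (magnitude $2^{\pm 2}$ by default), and
transgressive loci receive one with probability `fracParentalDE`.
Polyploid means follow the operational definitions: mid-parent for
additivity, one parent's mean for ELD, and the configured magnitude
beyond the extreme parent for transgressive loci. The realised
parental-DE fraction therefore emerges from the pattern mixture rather
than being set independently — the price of keeping every locus's truth
labels mutually consistent.

What the generator does **not** emulate: gene-length effects, correlated
loci, GC/mappability artefacts, population-level expression variation
between individuals, partial homeolog loss or gene conversion, and
isoform-level complexity. Passing the recovery tests therefore shows that
the estimators are correct under the stated model, not that real
inflorescence libraries satisfy that model.

`simulateHitTable()` builds reciprocal BLAST-style tables in which every
true pair is the reciprocal best hit by construction (decoys score below
100 bits with 40–70% identity and sub-200-bp alignments, so they also
violate every similarity filter), plus an optional fraction of unpaired
transcripts.

# Ortholog calling

Best hit = maximal bitscore, ties broken by minimal E-value, then
lexicographically smallest subject id (a stated, deterministic convention;
the tie-break convention used by the original searches is unknowable from
hit tables alone). Self-hits are ignored; a query without hits yields no
pair. The similarity filter ($E \le 10^{-10}$, identity $\ge 80$%, length
$\ge 200$ bp, all inclusive) applies by default to the B-as-query
direction, mirroring the convention of filtering on the search that used
the second parent as query; `direction = "both"` is available for stricter
replication. Filtering is monotone — tightening a threshold never adds a
pair — and RBH output is symmetric under exchanging the two tables.

# Enrichment

Term enrichment is hypergeometric by default, against the background of
loci actually used in the upstream test. With gene lengths supplied, the
null resamples target-sized gene sets with probability proportional to a
monotone (isotonic) fit of target membership against length — an explicit
resampling replacement for the Wallenius approximation that is equivalent
in the equal-weights limit (verified by test) — with $+1$ smoothing so no
empirical p is zero. Constant lengths reduce exactly to uniform weights.
No GO-graph propagation is performed; term ancestors are the user's
responsibility.

# Problem sizes and runtime

The test suite and acceptance script use the sizes the methods are
designed around: 2,000 loci for parameter recovery (bias classification
$\ge 90$% correct at $|\theta - 0.5| \ge 0.15$, false-bias rate
$\le 7.5$%, pattern recovery $\ge 85$% for loci whose simulated contrasts
are all at least two-fold), 5,000 loci for null calibration, and 10,000
loci for generator-composition checks. The whole suite runs in well under
a minute on one CPU; the grid posterior handles 2,000 loci in about two
seconds because the likelihood collapses to per-locus sufficient
statistics.

# Known limitations

* The conditional-binomial formulation discards information in the
  replicate totals about *total* expression — by design, since total
  expression is analysed separately by the DE engine.
* A single global $(q_A, q_B)$ (or per-locus pair) is shared across
  replicates; lane-specific misassignment is not identifiable from the
  supported inputs.
* The NB engine supports two-group and MPV contrasts only — no covariates,
  no interaction designs.
* Fold-change shrinkage is not implemented; `log2_fc` is a display
  quantity with a pseudocount, and inference rests on the Wald statistic.
* The enrichment test treats terms independently; no hierarchy-aware
  correction is attempted.
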