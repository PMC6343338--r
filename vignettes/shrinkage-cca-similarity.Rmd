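---
title: "Shrinkage canonical-correlation similarity for replicated poly(A)-site data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinkage canonical-correlation similarity for replicated poly(A)-site data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apacca)
```

## The problem

Alternative polyadenylation (APA) lets one gene produce transcript
isoforms that end at different poly(A) sites.  3′-end sequencing
quantifies each site separately, so a gene measured across `T`
experiments (tissues, conditions, time points) with `R(t)` replicates
each is not a single expression profile but a small *block* of site
profiles.  Summing the sites back into one gene-level value, as a
Pearson-correlation analysis must, discards exactly the within-gene
signal that 3′ sequencing was run to capture.  This package quantifies
the association between two genes from their full site blocks, and
feeds the resulting similarity matrix into clustering, cluster
validation and network summaries.

## The similarity model

Write `D[i, t, r]` for the measurement of site `i` in replicate `r` of
experiment `t`.  The model has three layers.

**1. Shrinkage of the replicate variance.**  For every site and
experiment we take the replicate mean `E[m, t]` and the unbiased
variance `K2[m, t]`.  With few replicates (2–3 is the norm) the
per-experiment variances are individually unreliable; following the
linear-regularization idea used for shrinkage correlation of
replicated microarrays, they are blended with the pooled,
degree-of-freedom-weighted variance

    Kbar2[m] = sum_t ((R(t) - 1) / (R - T)) * K2[m, t]

through a data-driven factor chosen by quadratic loss,

    rho = sum_t (1 - (R(t)-1)/(R-T)) * var(K2[m, t])
          / sum_t (K2[m, t] - Kbar2[m])^2 ,

clipped to `[0, 1]`.  The shrunk variance
`W*[m, t] = (1 - rho*) K2[m, t] + rho* Kbar2[m]` yields the *shrinkage
error* `psi[m, t] = sqrt(W*[m, t] / R(t))`, the standard error of the
experiment mean under the shrunk variance.  `rho* = 0` keeps the raw
variances, `rho* = 1` is full pooling; when all experiment variances
coincide the denominator vanishes and we define `rho* = 1`, the
continuous limit.

**2. Error-weighted site correlation.**  Each site's experiment means
are centred at the precision-weighted grand mean
`E_scca[m] = sum_t E[m,t]/psi[m,t]^2 / sum_t 1/psi[m,t]^2` and scaled
by `psi[m, t]`; the correlation `lambda[m, n]` of two sites is the
cosine of these standardized deviation vectors.  Experiments measured
precisely therefore dominate the correlation, experiments with noisy
replicates are down-weighted.  With constant `psi` this is exactly the
Pearson correlation of the experiment means.  When no experiment is
replicated at all the shrinkage layer has zero degrees of freedom;
the package then sets `psi = 1` everywhere, and `lambda` reduces to
the plain correlation of per-experiment values.

**3. Canonical correlation and significance weighting.**  For genes
`P` (m sites) and `Q` (n sites) the `lambda` values fill the block
correlation matrix with within blocks `S_PP`, `S_QQ` and cross block
`S_PQ`.  The squared canonical correlations `xi_1^2 >= ... >= xi_k^2`,
`k = min(m, n)`, are the eigenvalues of
`S_PP^-1 S_PQ S_QQ^-1 S_QP`.  Each coefficient is tested with the
Bartlett-style sequential likelihood-ratio statistic

    chi2_c = -(g - (m + n)/2) * sum_{i = c..k} log(1 - xi_i^2) ,

with `(m - c + 1)(n - c + 1)` degrees of freedom; coefficient `c`
counts as significant only if tests `1..c` all reject, and testing
stops at the first acceptance.  The gene-pair weight combines the
significant run, each coefficient weighted by `-log p`:

    w = sum_c xi_c * L_c / sum_c L_c ,   L_c = -log(p_c) if p_c <= 0.05 else 0 .

`w` lies in `[0, xi_1]`; with a single significant coefficient it is
exactly `xi_1`, and with none it is 0.

### The effective sample size `g`

The statistic needs the sample size over which the correlations were
estimated.  This package uses `g = R`, the total number of samples,
because the canonical problem is posed on the full replicate-level
measurement blocks — the shrinkage correlation is a sample correlation
in a transformed coordinate system that uses every replicate, not just
the `T` experiment means.  The alternative reading `g = T` makes the
multiplier `g - (m + n)/2` so small at realistic designs (e.g. `T = 8`
with three-to-four-site genes) that canonical correlations of 0.99 are
still declared non-significant against chi-squared critical values at
9–16 degrees of freedom; under that reading the method has essentially
no power for multi-site genes, which contradicts its intended use.
Under no replication `R = T` and the two readings coincide.  Users who
want a stricter test can simply lower `alpha`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 5 | minimum total read support per site before a site is kept |
| `mode` (quantification) | abundance | `abundance` keeps counts; `relative` converts to per-gene site-usage fractions |
| `alpha` | 0.05 | level of the sequential canonical tests; also the `-log p` cutoff in the weight |
| `workers` | 1 | process-level parallelism over gene pairs; results are identical for any value |
| `linkage` | complete | agglomeration rule of `hclust` |
| `k_range` | 5:20 | candidate cluster numbers for the silhouette criterion |
| `L` | 10 | nearest-neighbour count of the connectivity index |
| `tau` | 0.5 | binarization threshold of the network summaries |
| `threshold` | 0.7 | eigengene correlation above which a gene is a hub |

Filtering removes sites with fewer than `min_reads` reads in total
over all samples (the only numeric support rule we impose; per-sample
thresholds are not used) and genes left with fewer than two sites.
Selection of genes by external differential-usage testing, and removal
of intergenic sites, both need external resources and are accepted as
a pre-computed `gene_list`.

## Distance, clustering, validation

Weights are turned into distances as `d = 1 - w`.  Clustering is
complete-linkage `hclust`; the number of clusters is chosen by the
mean silhouette width over `k_range` (ties to the smallest k).  Five
validation indices are implemented from their definitions and
cross-checked in the test suite against independent brute-force
re-implementations: connectivity (penalty `1/j` when the j-th nearest
neighbour is in a foreign cluster; ties broken by index), the Dunn
index (minimum separation over maximum diameter), the stability
indices AD and ADM (each experiment deleted in turn with all its
replicates — deleting single replicate columns would break the
design — the similarity recomputed and re-clustered at the same k),
and the biological homogeneity index (fraction of ordered annotated
gene pairs within a cluster sharing a functional class, averaged over
clusters with at least two annotated genes).  For ADM the cluster
centres are mean gene-level expression profiles (site counts summed
per gene, replicates averaged per experiment): the weight matrix is
not a vector space, so centres need a coordinate representation, and
gene-level expression over experiments is the natural one.  Raw scores
are min–max normalized over all compared (method, k) cells with
lower-is-better metrics flipped, so larger is always better; constant
columns map to 0.5.

Network summaries binarize the weight matrix at `w > tau` and report
mean eigenvector centrality, the mean local clustering coefficient
over nodes of degree at least 2, and the Newman modularity of a given
module partition (the module-quality measure here; the literature pins
no single formula).  Module eigengenes are first principal components
of standardized within-module profiles, sign-fixed so the mean member
correlation is non-negative.

## The synthetic generator

The simulator follows a two-step scheme.  Per gene, site-usage
probabilities `p(i)` and a total depth `N` either come from observed
counts (`profile_from_counts`: `p(i) = a(i)/sum(a)`, `N = sum(a)`) or
are drawn (symmetric Dirichlet usage, log-normal depth).  Per
experiment each site's abundance is `Binomial(N, p_i)` —
independently per site, exactly as specified, so simulated site counts
need not sum to `N` — and each replicate adds normal noise, rounded
and clipped at zero.  The noise standard deviation defaults to
`0.5 * sqrt(base + 1)`, a Poisson-like heteroscedastic spread chosen
because count noise grows with the mean; a fixed `noise_sd` can be
supplied instead when empirical error levels are available.

The planted-cluster variant gives all genes of a cluster a shared
per-experiment vector that shifts their site-usage log-odds through
fixed centred site loadings: co-clustered genes co-vary across
experiments while keeping independent count draws.  At `effect = 0`
no structure exists and clusterings agree with the truth only at
chance level.

What the generator emulates: binomially over-dispersed site counts
whose usage fractions drift across conditions, replicate noise, and
block-structured co-variation.  What it does not emulate: library-size
differences between samples, correlated (multinomial) site draws,
gene-level expression shifts between conditions, and annotation-linked
cluster structure.  Passing recovery tests therefore show that the
pipeline detects usage-space co-variation under count noise — not
that it handles arbitrary real-data artefacts.

### The recovery experiment

The planted-recovery experiment in the test suite and the acceptance
script is a *positive control*, and its design follows a power
analysis rather than the generator defaults.  Three conditions make
recovery well-posed:

* **two-site genes** — the sequential statistic's multiplier
  `g - (m + n)/2` must stay large relative to the chi-squared critical
  value at `(m)(n)` degrees of freedom, which at `T = 8`, `R(t) = 3`
  requires the smallest blocks;
* **balanced usage and uniform depth** (Dirichlet concentration 5,
  depth 1000) — a gene whose minor site carries 2% of the reads has
  almost no usage signal at any effect size, and a single
  non-significant within-cluster pair puts a distance of exactly 1
  inside a cluster, which greedy complete linkage cannot absorb;
* **relative quantification** — the planted signal lives in usage
  space, so the analysis is run on site-usage fractions.

Under these conditions (150 genes, 3 clusters, `T = 8`, `R = 3`,
log-odds effect 1.5, noise scale 0.5) the pipeline recovers the
planted partition and the silhouette criterion selects `k = 3`; the
acceptance script recomputes both from scratch.  The comparison
against the gene-level Pearson engine estimates each method's best k
by silhouette and then scores connectivity and the Dunn index on each
method's own distance matrix, mirroring how internal validation is
conventionally reported.  The general-purpose generator defaults
(2–4 sites, Dirichlet concentration 1, log-normal depth) deliberately
include weak genes and are *not* tuned for recovery.

## Numerical choices

* `psi` is floored at `1e-6 * max(1, max_t |E[m, t]|)` so that
  zero-replicate-variance sites cannot produce infinities in the
  correlation.
* Block inverses use the Moore–Penrose pseudo-inverse with relative
  singular-value tolerance `1e-10`; exactly collinear blocks (two-site
  relative usage sums to 1) are handled without error.
* Eigenvalues are clipped to `[0, 1 - 1e-12]` before the square root,
  keeping `log(1 - xi^2)` finite; p-values are floored at `1e-300`
  before the logarithm.
* Self-pairs are excluded (diagonal fixed at 1): a gene against itself
  has `xi_1 = 1`, where the test statistic is singular.
* Degenerate sites (all standardized deviations zero) correlate 0
  with everything.
* Ties: nearest-neighbour ties in connectivity go to the smaller
  index; silhouette ties go to the smallest k; equal weights in the
  edge export are ordered lexically.
* The `-log p` weighting uses the natural logarithm; any fixed base
  rescales numerator and denominator terms consistently, and `e`
  matches the chi-squared derivation.

## Problem sizes in the shipped tests

Unit tests run on 3–25-gene instances; the oracle comparison uses 200
random block matrices with up to five sites per gene; the recovery and
comparison experiments use 150 and 10 × 60 genes at `T = 8`, `R = 3`.
These sizes were chosen so that every independent brute-force oracle
can be evaluated exactly alongside the implementation.

## Known limitations

* With `T` experiments the site correlations rest on `T` points;
  canonical correlations of blocks with `m + n` approaching `T` are
  strongly inflated, and only the significance test guards against
  them.  Designs with `(m + n)/2 >= R` are rejected outright.
* The weight of a non-significant pair is exactly 0, i.e. distance 1.
  Complete-linkage clusters fracture when such pairs occur inside a
  true cluster; on data with many weak genes a different linkage or a
  pre-filter of low-signal genes is advisable.
* Module detection here is a plain agglomerative cut plus an adjacency
  export; dedicated co-expression network tools with soft thresholding
  and topological-overlap measures are out of scope.
* Differential site-usage testing, genome-annotation handling and
  read-level simulation are out of scope.
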