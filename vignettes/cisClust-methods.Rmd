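---
title: "Intra-chromosomal co-expression clustering: model and methods"
author: "cisClust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra-chromosomal co-expression clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisClust)
```

# The problem

Tumor transcriptomes show a characteristic *loss of long-range
co-expression*: the strongest gene–gene correlations concentrate between
genes on the same chromosome (*cis-*), and even within a chromosome the
positive correlations decay as the genomic distance between gene pairs
grows. In healthy control tissue the correlation structure is largely
distance-independent. Most analyses of this phenomenon threshold the
co-expression network and study only the top fraction of edges; cisClust
instead works with the **whole** intra-chromosomal correlation matrix —
every gene pair on a chromosome — and asks two questions per chromosome and
phenotype:

1. How many gene clusters does the correlation matrix support, beyond what
   pure noise would produce?
2. Are those clusters localized along the chromosome (cancer-like) or
   scattered (control-like)?

# The method

## Correlation matrices

For each chromosome the Pearson correlation
$$C_{ij} = \frac{\mathrm{Cov}(g_i, g_j)}{\sigma_{g_i}\,\sigma_{g_j}}$$
is computed between every pair of genes over the $N_s$ samples of one
phenotype (`pearsonMatrix()`). The population normalization $1/N_s$ is used
in the covariance and the standard deviations; since it cancels in the
ratio, the matrix equals the ordinary sample correlation — the choice only
matters if the variance intermediates are inspected. Genes with zero
variance have no defined correlation and are removed when tables are read
(`readExpressionTable()`).

Gene coordinates come from a BED file; the 0-based BED start is used
verbatim as the gene position, genes are ordered by (chromosome, start,
gene id) — the id breaking ties for determinism — and each gene receives a
0-based ordinal *rank* along its chromosome. Distances between genes are
either base-pair differences of starts (`metric = "bp"`, the physical
view used for correlation–distance profiles) or rank differences
(`metric = "rank"`, the index view used by the nearest-neighbor
statistics, which are defined on gene order rather than physical length).

## The shuffled random-matrix null

How large can a correlation or an eigenvalue be when there is *no*
correlation structure at all? The package answers this empirically with an
ensemble of $n_m = 100$ shuffled copies of the expression matrix
(`buildNullEnsemble()`): each copy permutes the observed values so that
every gene keeps its marginal distribution while all gene–gene dependence
is destroyed, then the full correlation matrix and its eigenvalue spectrum
are computed exactly as for the real data. The pooled spectrum of such an
ensemble follows the Marchenko–Pastur law with aspect ratio
$q = N_\mathrm{genes}/N_s$ and support $[(1-\sqrt q)^2, (1+\sqrt q)^2]$;
`mpDensity()`/`mpCDF()` provide the analytic reference, and the test suite
verifies the agreement (Kolmogorov distance of the pooled spectrum to the
analytic CDF below 0.05 at 200 genes × 400 samples × 100 members).

**Choice of shuffle axis.** Shuffling can permute each gene's values across
samples (`within = "gene"`, the default) or each sample's values across
genes (`within = "sample"`). Both destroy gene–gene correlation, but they
preserve different marginals. The per-gene axis is the package default
because it is the null that matches the statistic under study: each gene
keeps exactly the marginal that enters $C_{ij}$, and *all* cross-gene
dependence is removed. The per-sample axis preserves each sample's value
multiset instead — which sounds appealing — but any variation of the
per-sample mean (sample-to-sample location differences, which arise
generically whenever expression is not strictly sample-normalized, and in
the synthetic factor model have variance `loading/nBlocks`) survives that
shuffle as a component shared by *all* genes. The null's top eigenvalue
then grows like $N \cdot \mathrm{var}(\mu_s)$ and can reach the height of
the very spikes one is trying to detect, silently swallowing real
structure. On strictly sample-normalized data the two axes agree; the
per-sample axis remains available as an option.

## Deviating eigenvalues set the cluster number

The empirical spectrum is compared against the ensemble's per-member
largest eigenvalues: the threshold is their empirical $(1-\alpha)$ quantile
(lower order statistic; $\alpha = 0.01$ by default, so with 100 members the
threshold is the 99th percentile of maxima), and
$k$ = number of empirical eigenvalues strictly above it
(`countDeviatingEigenvalues()`). $\alpha = 0$ would degenerate to the
strict max-of-ensemble rule; the quantile form makes the false-positive
rate explicit. The smallest eigenvalues — the most noise-sensitive part of
the spectrum — are never used, and eigenvectors are deliberately not used
for cluster assignment: $k$ is handed to a clustering algorithm instead.
In a spiked-covariance model each planted factor contributes one eigenvalue
above the Marchenko–Pastur bulk, so $k$ recovers the factor count; the
acceptance suite verifies exact recovery of 5 planted blocks at loading
0.7 (150 genes × 300 samples) in at least 18 of 20 seeds. A chromosome
with $k = 0$ is a legitimate, null-like outcome and short-circuits to "no
clustering" rather than an error.

## k-medoids on the signed-correlation distance

Genes are clustered with the dissimilarity
$$D_{ij} = 1 - |C_{ij}|,$$
so strong correlation *or* anticorrelation both mean proximity
(`correlationToDissimilarity()`). Clustering is PAM-style k-medoids
(`kmedoidsOnce()`): $k$ initial medoids drawn uniformly without
replacement, then alternating assignment (nearest medoid; ties to the
lowest medoid index) and a swap step that accepts the single best
objective-improving medoid/non-medoid exchange, until no swap improves.
The objective is the mean gene-to-medoid dissimilarity. Because the
initialization is random, `kmedoidsBest()` repeats the run $n_r = 100$
times (restart $r$ seeded with `seed + r`) and keeps the configuration
with the minimal objective, ties resolved to the lowest restart index. On
8-gene instances the restarted search attains the exhaustively enumerated
optimum in ≥ 90 % of cases, and its objectives are never worse than
`cluster::pam`'s on shared instances (both checked in the tests).

## Spatial statistics

With cluster labels in hand, spatial organization is quantified by the
intra-cluster nearest-neighbor distance (NND): for each gene in a cluster
of size ≥ 2,
$$D^{nn}_i = \min_{j \in C_k,\, j \neq i} |j - i|,$$
with $i, j$ gene ranks (or positions under `metric = "bp"`). Singleton
clusters have no neighbor; they are excluded and counted. The pooled NND
distribution is summarized by its Shannon entropy
$H = -\sum_x p(x)\log p(x)$ over the distinct observed NND values — no
binning; low entropy means tight, contiguous clusters (cancer-like), high
entropy means scattered membership (control-like). Phenotypes are
contrasted by the exact two-sample Kolmogorov–Smirnov distance
$D_{KS} = \sup_x |F_n(x) - F_m(x)|$ between their pooled NND samples and
by the entropy difference (`comparePhenotypes()`).

The same KS distance drives the piece-wise comparison of correlation
values against the null (`piecewiseKSvsNull()`): gene pairs are binned
into equal-occupancy distance windows, and per window the empirical
correlation values are compared with the pooled values of shuffled-null
matrices for the same pairs. Significance is assessed by permutation —
pooled values are randomly re-split at the original sizes, with the
add-one correction $(b+1)/(n_{\mathrm{res}}+1)$ so p-values are never
exactly zero — and Benjamini–Hochberg adjusted across windows. The
across-window *average* p-value is also emitted for comparability with
the way such profiles are often summarized, but it is flagged as a
summary, not a test. In decaying (cancer-like) data the window KS
statistic falls with distance; in control-like data the deviation from
the null persists at all distances.

# Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `nNull` ($n_m$) | 100 | shuffled matrices per chromosome and phenotype |
| `alpha` | 0.01 | tail probability of the deviating-eigenvalue threshold |
| `nRestarts` ($n_r$) | 100 | k-medoids restarts per clustering |
| `nWindows` | 50 | equal-occupancy distance windows |
| `nResamples` | 1000 | permutations per window KS test |
| `metric` | rank | distance units for NND statistics |
| `entropyBase` | e | natural-log entropy; bits via `"2"` |

Equal-occupancy (quantile) windows are used rather than equal-width ones
because the density of gene pairs varies strongly with distance; every
window then carries the same sample size. Positive and negative
correlations are summarized separately in profiles, because the
distance-decay phenomenon concerns positive correlations specifically.

# The synthetic generator

`simulateExpression()` provides ground truth for every downstream stage.
Gene positions are drawn uniformly without replacement on the chromosome
(default 100 Mb — a chromosome-scale span) and sorted; expression values
follow one of four modes:

* **blocks** (cancer-like): genes form `nBlocks` *contiguous* runs, each
  sharing a per-sample standard-Gaussian factor:
  $x_{gs} = \sqrt{\lambda} f_{b(g),s} + \sqrt{1-\lambda}\,\epsilon_{gs}$.
  With unit noise the population within-block correlation equals the
  loading $\lambda$, cross-block correlation is 0, and the correlation
  matrix has exactly one deviating eigenvalue per block — closed forms
  that `expectedCorrelation()` exposes and the tests exploit.
* **control** (control-like): the same factor model but genes are assigned
  to factors uniformly at random regardless of position, and a fraction
  (`negFraction`, default 0.3) enters with negated loading, planting
  significant anticorrelations; correlation structure is
  distance-independent by construction.
* **decay**: a Gaussian process over gene positions with covariance
  $\lambda e^{-d/\xi} + (1-\lambda)\delta_{ij}$ — smooth correlation decay
  with distance at scale $\xi$ (`decayScaleBp`).
* **null**: i.i.d. Gaussians.

Defaults (150 genes × 300 samples, 5 factors, loading 0.7, unit noise)
describe a regime where the spectral count and the clustering both recover
the planted structure while leaving genuine stochastic variation across
seeds. A factor/Gaussian-process model was chosen because it yields exact
population correlations and a known spike count; it emulates the
*correlation geometry* of the data, not RNA-Seq marginals — values are
continuous log-scale surrogates, not negative-binomial counts, there is no
library-size or GC structure, and no cross-chromosome linkage. Passing
tests therefore certify the inference machinery (spectral counting,
clustering, spatial statistics), not robustness to count noise or
normalization artifacts.

All randomness derives from one master seed: positions, structural
assignments and values use separate sub-streams (`seed`, `seed + 1`,
`seed + 2`), so changing the number of samples never moves gene positions.
The pipeline (`runPipeline()`) derives per-stage seeds by hashing the
master seed with the stage name, chromosome and phenotype, so adding a
chromosome or phenotype never changes another cell's results, and two runs
with the same configuration are byte-identical.

# Numerical choices, edge cases, validation sizes

* Correlation matrices are exactly symmetrized ($((C + C^\top)/2$) with the
  diagonal forced to 1; eigenvalues are clipped at 0 (removing
  $-10^{-15}$-scale round-off) and rescaled to preserve the exact trace.
* The decay-mode Gaussian process adds a $10^{-10}$ jitter before the
  Cholesky factorization and errors if the covariance still fails.
* Ties: equal start coordinates are ordered by gene id; equal dissimilarity
  in assignment goes to the lowest medoid index; equal objectives across
  restarts go to the lowest restart index; the distance-window assignment
  orders tied distances stably.
* The strict `mean > threshold` expression filter defaults to *off* in the
  pipeline, because inputs are normally preprocessed upstream; when used,
  the conventional count-scale threshold is 10 and applies to whatever
  scale the caller supplies.
* Validation problem sizes: the oracle-equivalence checks run on matrices
  up to 30×30; spectral checks use 200×400 (Marchenko–Pastur), 60×120
  (null-on-null, 100 independent ensembles) and 150×300 (factor recovery,
  20 seeds); clustering optimality uses 8-gene exhaustive enumeration (100
  instances) and 150-gene planted partitions; the profile/KS dichotomy and
  the entropy/KS contrasts use 100–120 genes × 300–500 samples over 20
  seeds. These sizes estimate each property with comfortable margins while
  keeping the whole suite fast on a single CPU.
* Window medians at the decay tail sit at the positive-noise floor, and
  extreme-distance windows draw their pairs from few distinct genes, so
  successive medians there co-fluctuate at the ±0.02 scale; profile decay
  is therefore assessed as a negative rank trend of the window medians
  (plus a net first-to-last drop) rather than elementwise monotonicity,
  mirroring how the KS-versus-distance trend is assessed.

# Known limitations

* The method is intra-chromosomal by design; *trans-* structure is out of
  scope, as are Spearman or mutual-information association measures.
* $k$ counts every deviating eigenvalue, including a global
  market-mode-like component if present; on data with a strong common mode
  one cluster may absorb it.
* The permutation p-value resolution is $1/(n_{\mathrm{res}}+1)$; window
  counts below 2 on either side yield `NA` p-values (logged).
* The restarts carry no significance test: they are an optimization
  device, and no p-value is attached to the chosen configuration.
* Real-data concerns — normalization, batch effects, subtype calling,
  copy-number confounding — are upstream of this package and unaddressed
  by the synthetic validation.
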