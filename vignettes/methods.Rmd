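---
title: "Inference and enrichment methods in grngpea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference and enrichment methods in grngpea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grngpea)
```

# What the package computes

`grngpea` reconstructs an undirected gene regulatory network (GRN) from a
gene-by-sample expression matrix, asks which predefined gene sets are
over-represented among the network's edges, summarizes the network's
structure, and quantifies its agreement with reference interaction networks.
Everything is exercised against a synthetic benchmark whose ground truth is
known, so each claim the pipeline makes can be checked.

# The dependency score

Pairwise dependency between gene profiles is measured by mutual information
under a bivariate Gaussian model, where it is a closed form of the Pearson
correlation $\rho$:

$$I(X,Y) = -\tfrac{1}{2}\,\log\!\left(1-\rho^2\right).$$

This "Pearson estimator" is monotone in $|\rho|$, so rankings of partners
are rankings of absolute correlation; the MI form matters because the
inference rule and its permutation null are formulated on the MI scale.
$\rho^2$ is capped at $1-10^{-12}$ so duplicated profiles yield a large
finite score instead of an infinity. Correlations use the sample ($n-1$)
denominator; this cancels in $\rho$ and is noted only for completeness.

# C3Net and the permutation null

C3Net keeps, for each gene, only the single partner with the largest MI —
at most one candidate per gene, hence at most $p$ edges for $p$ genes.
A candidate survives only if its MI is significant against a permutation
null: the pool is built by repeatedly drawing a random gene pair and
independently permuting each gene's sample order, which destroys any
dependence while preserving both marginals. The empirical p-value uses the
+1 correction, $p = (1+\#\{\text{pool} \ge I\})/(n_{\text{draws}}+1)$, and
is Bonferroni-multiplied by the number of candidate genes. One pool of
100,000 draws (configurable) per dataset is shared across all tests; the
per-edge empirical p-value is one of two readings of the procedure (the
alternative being a single global MI cutoff) and is the one implemented.

Argmax ties are broken by the lexicographically smallest partner
identifier, so results are identical across platforms. Constant genes are
an error in user-facing calls; inside the bootstrap ensemble (where
resampling can flatten a gene that varies in the original data) they are
silently excluded from candidacy.

# BC3Net: bagging and the consensus test

BC3Net runs C3Net on $B$ bootstrap datasets (samples drawn with
replacement, size preserved; default $B=100$) and aggregates the ensemble.
Each aggregated edge carries its ensemble consensus rate (ECR), the
fraction of bootstrap networks containing it. Whether an edge's count
$k_e$ is larger than chance is assessed with a one-sided binomial test
against $\mathrm{Binom}(B,\theta_0)$. The null rate $\theta_0$ is not part
of the published procedure; the package estimates it self-calibratingly as
the expected per-pair occurrence rate
$\theta_0 = \sum_e k_e / (B \cdot N)$ with $N = p(p-1)/2$, which requires
no extra parameter. Binomial p-values are Bonferroni-corrected by the
number of distinct aggregated edges; edges with adjusted $p \le 0.05$ are
retained. Bootstrap index streams are a pure function of `(seed, b)`, so
the ensemble is reproducible regardless of evaluation order, and
resampling is assumed to act on samples only.

Two relevance-network baselines are provided: hard thresholds on the
absolute correlation matrix, and on the CLR score
$\sqrt{\max(0,z_i)^2+\max(0,z_j)^2}$ of per-gene MI z-scores. The
threshold is the requested percentile of all off-diagonal scores; pairs
strictly above it become edges, which keeps exactly
$\lceil (1-q)N \rceil$ pairs for distinct scores and returns an empty
network in the $q \to 1$ limit.

# Gene-pair enrichment analysis (GPEA)

For a universe of $p$ network genes there are $N = p(p-1)/2$ gene pairs; a
set of $p_S$ genes contains $m_S = p_S(p_S-1)/2$ of them. If the network
has $n$ edges of which $k$ fall inside the set, the enrichment p-value is
the hypergeometric upper tail

$$p(k\,|\,S) = \sum_{i=k}^{m_S}
\frac{\binom{m_S}{i}\binom{N-m_S}{n-i}}{\binom{N}{n}},$$

evaluated in log space (log-binomials combined by log-sum-exp) so that
tail probabilities far below double precision underflow thresholds remain
accurate relative to their own magnitude. The universe is deliberately the
network's node set — only network genes can form edges — and set members
are intersected with it before $p_S$ is counted. P-values are corrected
over the number of tested sets; the default is Bonferroni with a stringent
significance level of $0.001$, appropriate when the number of sets is in
the thousands (functional collections); Benjamini–Hochberg FDR is
available and is the choice used for subnetwork comparison p-values. The
composition "adjusted $p \le 0.001$" is one reading of pairing a stringent
level with Bonferroni; both knobs are exposed.

Gene sets come from three sources: functional collections (GMT files),
gene families (GMT), and genomic co-location — 1 Mb windows tiled every
500 kb along each chromosome, a gene belonging to a window when its start
coordinate falls inside it. Start-coordinate assignment is a single
unambiguous rule (midpoint or overlap rules would differ only for genes
spanning a window boundary); windows are anchored at coordinate 0 per
chromosome, and windows with fewer than 3 genes are dropped. Coordinates
are 0-based half-open internally; 1-based input is converted at the file
boundary.

A secondary, gene-based census enrichment asks whether the genes incident
to a significant subnetwork's edges are enriched for a curated gene list
(one-sided hypergeometric over genes). It is gene-based rather than
pair-based because the census annotates genes, not interactions.

# Network structure and comparison

Structural summaries are degree centrality (hub tables are ordered by
degree descending, identifier ascending), edge density $n_e/\binom{n}{2}$,
the giant connected component (ties broken by smallest lexicographic
member), the degree power-law exponent, and the average shortest path on
the giant component. Edges are unweighted, so breadth-first-search
distances equal Dijkstra distances; graphs above 2,000 nodes use a seeded
uniform sample of 10,000 node pairs instead of all pairs, trading
exactness for runtime (tests retain an exact-vs-sampled check). The
power-law exponent uses the fixed-`xmin` maximum-likelihood estimate with
the continuous approximation $\hat\alpha = 1 + n/\sum_i
\ln(d_i/(x_{\min}-\tfrac12))$. That approximation is accurate when
$x_{\min}$ is a few units or more; fitting from the very first degree of a
steep discrete distribution biases it downward, so analyses here fit the
tail ($x_{\min} = 3$ on inferred networks) — the choice of fitting regime
is the package's own, as the estimator's regime is not prescribed
anywhere.

Network-versus-network agreement uses: shared edges over the union of
edges (on the shared node universe; triple intersection over triple union
for three networks); a hypergeometric shared-edge test that reuses the
GPEA kernel (population $\binom{u}{2}$ pairs, successes $|E_a|$, draws
$|E_b|$); and confusion metrics TP/FP/TN/FN with precision, recall and
F-score $F = 2PR/(P+R)$, with $F = 0$ by convention when $P+R = 0$ so
F-score distributions are always defined. The comparison universe defaults
to the node intersection — using the union would count coverage
differences as disagreement — but the union is available for global-table
style comparisons. Per-gene-set comparisons induce both networks on the
set's members; sets whose reference subnetwork has no edges are skipped
and counted, because a comparison against an empty reference is
uninformative. Chance level comes from repeating the comparison against
25 versions of the reference with uniformly permuted node labels, which
preserves the reference topology while destroying specific agreement.
Where a log-transformed F-score distribution is wanted, zeros are handled
with an offset of $10^{-3}$.

# The synthetic benchmark

The generator exists because the analyses the package implements were
designed for tumor expression cohorts that cannot be bundled; it plants a
known truth with the statistical structure the inference stack assumes.

**Planted network.** Degrees are drawn from a truncated discrete power law
with exponent 4 (inferred regulatory networks typically show exponents
near 4) and realized by a configuration model with self-loops and
multi-edges removed. The minimum degree is 2: with minimum degree 1 a
power law this steep sits below the Molloy–Reed percolation threshold and
has no giant component, while the generated truth is required to be
$\ge 90\%$ connected. Each edge carries a strength drawn uniformly from
$[0.25, 0.4]$ on the partial-correlation scale.

**Expression.** Latent profiles follow the Gaussian graphical model whose
precision matrix has $-\text{strength}$ at planted edges and a diagonally
dominant diagonal (row sum of absolute off-diagonals plus a margin of 0.1,
guaranteeing positive definiteness while staying away from singularity).
A GGM is the right stand-in here because the inference stack measures
pairwise dependency through correlation, so planted edges are the
strongest marginal dependencies — matching the detectability assumption of
the maximal-neighbor rule. The RNAseq observation layer maps the latent
value through $\mathrm{round}(\exp(0.7z+4))$ and returns `log1p` of the
count, spanning a realistic count range of roughly 5–500; the array layer
adds Gaussian noise with SD 0.1 on the intensity scale. Defaults are 500
genes and 180 samples, the scale of the tumor cohorts this kind of
analysis is run on, scaled to desk-size.

**Planted signal.** True gene sets are connected subgraphs grown by
breadth-first search, grown disjointly (each search is restricted to genes
not yet used) so that every planted signal — and its genomic co-location —
is well defined; null sets are uniform random samples of matched sizes.
Half of the true sets are made chromosomally co-located: their members are
placed contiguously from a 1 Mb window boundary (spacing 100 kb, shrunk if
needed to fit the window) with a one-window gap before unrelated genes;
everything else is shuffled onto synthetic chromosomes of 100 genes. The
reference network removes 30% of true edges and adds an equal number of
random non-edges, emulating an incomplete and partly wrong external
interaction database.

A single master seed fans out to per-stage child seeds by fixed offsets,
so each stage is independently reproducible.

What the generator does **not** emulate: RNAseq library-size and GC
artifacts, probe-level array effects, tumor clonal heterogeneity, and
indirect-regulation confounding beyond what the GGM induces. Passing the
benchmark therefore shows the machinery is correct and sensitive under its
own model assumptions; it does not certify performance on real tumor
cohorts.

# Validation design and problem sizes

The test suite validates each layer against an independent oracle:
brute-force straight-line reimplementations of C3Net and BC3Net consuming
the same bootstrap index streams; exhaustive enumeration of the
hypergeometric tail for small universes plus agreement with R's `phyper`
to $10^{-9}$ relative error on random cases; calibration of raw GPEA
p-values on label-shuffled sets (fraction below 0.05 within $5\%\pm2\%$);
and planted-signal recovery on ten replicate benchmarks (500 genes, 180
samples, $B=50$, null pool 25,000 draws — sizes chosen so the whole suite
runs on a laptop-scale machine). Recovery is asserted by rank: every
planted set must attain a smaller adjusted p-value than every size-matched
null set, and every co-located set's window must outrank every window free
of planted signal. Rank separation is the right currency here because
absolute significance of a small set depends on how many of its handful of
edges the inference recovered — a set of six genes with three recovered
edges sits orders of magnitude below any noise window yet can miss a
stringent fixed threshold. The ensemble's global F-score against the truth
must also beat the mean of 25 label-randomized baselines in every
replicate, and the whole pipeline must reproduce byte-identical result
tables under a fixed configuration.

# Known limitations

* The Gaussian MI estimator sees only linear dependence; non-monotone
  regulation is invisible to the whole stack by construction.
* $\theta_0$ estimated from the ensemble itself makes the binomial test
  self-calibrating but means retention thresholds shift with overall
  ensemble density.
* Bonferroni across overlapping genomic windows is conservative, since
  adjacent windows share half their genes and are strongly dependent
  tests.
* The permutation pool is shared across bootstrap replicates for speed; a
  per-replicate pool would be marginally more faithful and substantially
  slower.
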