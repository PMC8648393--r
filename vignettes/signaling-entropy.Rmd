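---
title: "Signaling entropy on expression-weighted interaction networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signaling entropy on expression-weighted interaction networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(sigentropy))
```

## The model

`sigentropy` quantifies how promiscuously signaling can spread through a
protein–protein interaction (PPI) network given one sample's expression
profile. The premise is mass action: if genes $i$ and $j$ interact in the
network and both are highly expressed, signal flux along that edge is
likely. Undifferentiated and malignant cells, which keep many pathways
simultaneously active, should therefore support a faster-mixing signaling
process than differentiated tissue with a few specific pathways switched
on.

Formally, let $A$ be the symmetric 0/1 adjacency matrix of the PPI network
restricted to genes with expression data (largest connected component),
and $x > 0$ a sample's expression vector over those genes. Edge weights
$w_{ij} \propto x_i x_j$ on the edges of $A$, normalized per gene, give a
random-walk transition matrix

$$p_{ij} = \frac{x_j}{(Ax)_i}, \qquad j \in N(i),$$

whose stationary (invariant) distribution has the closed form

$$\lambda_i = \frac{x_i (Ax)_i}{x^\top A x}.$$

The walk satisfies detailed balance — $\lambda_i p_{ij} = \lambda_j p_{ji}
= A_{ij} x_i x_j / (x^\top A x)$ is symmetric by construction — so the
closed form is exact, not approximate. `transition_model()` always uses
the closed form; the fixed-point property $\lambda P = \lambda$ is used
only as a test of correctness.

The entropy rate of the walk is

$$\mathrm{Sr}(x) = -\sum_i \lambda_i \sum_{j \in N(i)} p_{ij} \log
p_{ij},$$

in nats. Its maximum over all walks on the same graph is attained by the
maximal-entropy random walk and equals $\log \Lambda_{\max}(A)$, the log
of the dominant adjacency eigenvalue ($\texttt{maxSr}$). The global
signaling entropy is the normalized rate

$$\mathrm{SR}(x) = \mathrm{Sr}(x) / \mathrm{maxSr} \in [0, 1],$$

and the local signaling entropy of gene $i$ is its contribution
$\mathrm{LSR}_i = -\lambda_i \sum_j p_{ij} \log p_{ij}$. We report LSR
after division by $\texttt{maxSr}$, so that $\sum_i \mathrm{LSR}_i =
\mathrm{SR}$ holds exactly. The unnormalized local values are retained in
`lsr_raw`. This normalization is the package's reconciliation of two
conventions — a raw per-node summand on the one hand and the statement
that the normalized SR is the *sum* of the local values on the other; with
it, LSR is a well-defined share decomposition of SR, and any ratio of
LSR to SR is identical under either convention because the
$1/\texttt{maxSr}$ factors cancel.

Useful analytic facts, all covered by tests:

* SR is invariant to rescaling $x \mapsto cx$ (every formula is
  homogeneous of degree 0), so RSEM-like abundance units do not matter.
* SR $= 1$ exactly when $x$ is the dominant adjacency eigenvector; on a
  regular graph (e.g. the triangle $K_3$) the uniform profile achieves
  this.
* On $K_3$ with $x = (1, 2, 3)$: $\lambda = (5, 8, 9)/22$, SR
  $\approx 0.8914$, LSR $\approx (0.2207, 0.2950, 0.3757)$ — a worked
  micro-example used throughout the test suite, cross-checked against a
  longhand evaluation and against the empirical per-step entropy of a
  simulated walk.

## Numerical choices

**Dominant eigenvalue.** `max_entropy_rate()` runs power iteration on
$A + I$ from the all-ones start vector to relative tolerance $10^{-10}$.
The unit shift makes the iteration convergent on bipartite graphs (paths,
trees), where the spectrum is symmetric and unshifted iteration would
oscillate between $\pm\Lambda_{\max}$. Dense `eigen()` and igraph's ARPACK
serve as independent oracles in the tests, never in the implementation.

**Zeros and pseudocounts.** $p_{ij}$ is undefined at a node whose
neighbours all have zero expression. `entropy_matrix()` therefore replaces
zeros with half the smallest positive entry of the matrix (configurable)
before building the walk. Entries of $P$ are then strictly positive on the
edge set, and the $0 \log 0 \equiv 0$ convention is enforced structurally:
only stored sparse entries are transformed.

**Sparse computation.** $P$ is never materialized densely in the driver
path; row entropies are computed on the sparse structure, so genome-scale
networks (tens of thousands of edges) cost milliseconds per sample.

**Proteome preprocessing.** TMT-style log-ratio matrices are z-scored per
column (population SD, so a two-value column $(-1, 1)$ maps to itself),
missing entries are filled with the protein's row median, all-missing
proteins are dropped with a warning, and values are mapped to positive
masses by $2^v$. The exponentiation base and the population-SD choice are
package decisions — the upstream convention for turning normalized
log-ratios into non-negative mass-action weights is not standardized —
and both are recorded in the function documentation. Because SR is
scale-free, the base affects only the relative spread of the weights, not
the admissibility of the result.

**Identifier handling.** Gene identifiers are matched by exact string
equality after whitespace trimming. No alias translation is attempted;
harmonize identifiers upstream.

## Downstream analyses

**Differential LSR (DLSR).** For each gene, `dlsr()` compares tumor
vs normal LSR with a pooled two-sample Student's *t* (Welch behind a
flag), BH-FDR across genes, and Cohen's *d* with the pooled unbiased SD
(tumor minus normal, so $d > 0$ means entropy gained in tumor). Genes
with $q < 0.05$ and $|d| > 1$ are classed up/down; both thresholds are
arguments. `consensus_features()` intersects per-cohort calls, keeping
genes consistently classed in at least `min_types` cohorts — the
mechanism for building a shared cross-cancer feature panel.
`ora()` is a plain upper-tail hypergeometric over-representation test
against user-supplied GMT collections; the default universe in the
drivers is the network node set, since only network genes can carry LSR.
Whether to prefer the network universe or a whole-genome universe is a
genuine judgment call; the network universe is the conservative choice
for LSR-derived gene lists because it conditions on eligibility.

**Stratification.** `hierarchical()` is UPGMA on Euclidean distances,
`kmeans_cluster()` is `stats::kmeans` with `nstart` restarts under a
fixed seed, and `chi_square_association()` is the Pearson chi-square
(no continuity correction) between cluster labels and a clinical factor.
Cohort-level clustering uses per-type mean SR / mean LSR
(`type_means()`). The number of clusters is a required user input —
nothing in the method selects $k$.

**Survival.** `fit_cox()` fits one multivariate Cox model on a
samples × features LSR matrix (Breslow ties by default, Efron and an
optional ridge penalty behind flags), refuses $p \ge n$ cohorts, and
reports Harrell's C (ties in the predictor count 1/2; with a two-valued
predictor the within-group tied pairs therefore cap C strictly below 1,
which is the correct behaviour, not a defect). No variable selection is
performed: features weak in one cohort are retained because they may
carry signal in another. The fitted model is re-applied to new cohorts
via its linear predictor only (`apply_cox()`), never refit. Risk groups
are a median split of the linear predictor with strict inequality for
the high arm, so an all-equal predictor degenerates to everyone-low.

**Drug response.** `binarize_ic50()` splits each drug's ln-IC50 vector
(natural log of µM IC50) into sensitive/resistant at the equal-posterior
crossing of a two-component Gaussian mixture; when model selection
prefers one component or the fit degenerates (vanishing weight, no
crossing between the means) it falls back to the median and flags the
record, so thresholds from other procedures can also be supplied
externally. `sr_drug_effect()` reports Cohen's *d* of SR, resistant
minus sensitive. `lsr_ratio()` computes each target's LSR share of SR —
a proportion in $[0, 1]$ summing to 1 over all genes — and
`ratio_ic50_correlation()` tests its Pearson association with ln-IC50,
optionally stratified by the target's mutation status.

## What the synthetic generators emulate

The generators exist so every stage can be exercised with known ground
truth and no external downloads; their defaults are the study conditions
used by the test suite and the acceptance script.

* `simulate_ppi()`: preferential attachment — a founding edge, then each
  new gene attaches to `m = 2` existing genes with probability
  proportional to degree, giving a connected, degree-heterogeneous
  (scale-free-like) graph of `n_genes = 1000` by default, the same
  qualitative degree structure as curated PPI databases.
* `simulate_expression()`: per-gene log-normal baselines (log-means
  $\mathcal{N}(\log 10, 1)$, per-sample log-noise $\sigma = 0.5$),
  two groups of 50 samples, and 20 planted genes multiplied by 4 in the
  tumor group. Planted genes are drawn uniformly at random; because a
  planted perturbation also shifts the walk around the gene, immediate
  neighbours can show secondary LSR shifts — at these settings the
  observed spill-over stays around ~1% of null genes, within the 5%
  false-call budget the recovery tests assert.
* `simulate_survival()`: exponential event times with hazard
  $h_0 \exp(\beta^\top z)$ on internally standardized features
  ($\beta = 0.8$, $h_0 = 0.01$), independent uniform censoring with the
  upper bound solved numerically to hit the configured censoring
  fraction (default 20%). The survival recovery condition uses a
  homogeneous 500-sample cohort on a 200-gene network with the hazard
  driven by the cohort's most variable LSR feature: an unimodal feature
  makes the concordance of the true model a stable quantity
  (C ≈ 0.69 at $\beta = 0.8$).
* `simulate_drug_panel()`: $\ln \mathrm{IC50} = 2 - 5 \cdot
  \mathrm{ratio} + \mathcal{N}(0, 0.5)$ over 100 cell lines, with an
  optional mixture shift to induce bimodality. The drug-response
  condition evaluates the ratio on a pathway-scale 15-gene network with
  the hub as the drug target, where the target's LSR share is large and
  variable (mean ≈ 0.37, SD ≈ 0.10); with slope 5 and noise 0.5 this
  yields a planted Pearson r around −0.7. On genome-scale networks a
  single gene's share is of order $1/n$ and a fixed slope-5 coupling
  would be numerically invisible — target pathways, not whole
  interactomes, are the natural scale for this score.

What the generators deliberately do **not** model: tumor purity and
stromal admixture, batch effects, microarray probe artifacts, single-cell
dropout, correlated gene modules beyond what the network walk itself
induces, and informative censoring. Passing recovery tests therefore
demonstrates the pipeline's correctness and sensitivity under clean
planted signal, not performance on real cohorts.

## Problem sizes and determinism

The default test and acceptance workloads are sized for interactive runs:
1000-gene networks with 100 samples for the differential analysis,
500-sample survival cohorts, 100-cell-line panels, a $10^6$-step
simulated walk for the entropy oracle, and 100 random draws for the
model-identity checks; the full suite completes in well under a minute.
Every stochastic step is seeded: generators take their seed from
`sim_config()`, and k-means records `n_starts` and seed in its metadata.
Re-running any command with the same inputs and seeds reproduces outputs
bit for bit.

## Known limitations

* The walk model assumes an undirected, unsigned, unweighted interaction
  scaffold; edge confidences and directionality are out of scope.
* LSR inherits the network's degree structure: hubs carry large shares.
  Comparisons should therefore be made per gene across samples (as the
  differential analysis does), not across genes within a sample.
* The equal-variance *t*-test and pooled Cohen's *d* are the defaults by
  convention; for strongly heteroskedastic group variances use the Welch
  flag.
* The Gaussian-mixture IC50 threshold is one defensible binarization;
  externally computed thresholds can be injected wherever labels are
  accepted.
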