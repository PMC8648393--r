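# sigentropy

Signaling entropy of expression-weighted protein–protein interaction
networks, with the downstream analyses that make it useful: differential
local entropy between tumor and normal tissue, entropy-feature survival
models, and drug-response scoring.

## The problem and the model

Undifferentiated and malignant cells keep many signaling pathways
simultaneously active; differentiated tissue activates a few specific
ones. `sigentropy` turns that intuition into a number. Given a PPI
network with adjacency $A$ and a sample's expression vector $x > 0$ over
the network genes, mass action ($w_{ij} \propto x_i x_j$ on edges)
defines a random walk

$$p_{ij} = \frac{x_j}{(Ax)_i}, \qquad
\lambda_i = \frac{x_i (Ax)_i}{x^\top A x},$$

where $\lambda$ is the exact stationary distribution (the walk obeys
detailed balance). The **global signaling entropy** is the normalized
entropy rate

$$\mathrm{SR}(x) = \frac{-\sum_i \lambda_i \sum_j p_{ij} \log p_{ij}}
{\log \Lambda_{\max}(A)} \in [0, 1],$$

with the denominator the maximal-entropy-walk bound (log of the dominant
adjacency eigenvalue). The **local signaling entropy** $\mathrm{LSR}_i$
is gene $i$'s contribution, normalized so $\sum_i \mathrm{LSR}_i =
\mathrm{SR}$. High SR means signaling can spread promiscuously; per-gene
LSR localizes where the entropy is gained or lost.

On top of the entropy core the package provides:

* `dlsr()` — per-gene differential LSR (pooled *t*, BH-FDR, Cohen's
  *d*, up/down calls at $q < 0.05$, $|d| > 1$), `consensus_features()`
  across cohorts, and hypergeometric `ora()` against GMT gene sets;
* `hierarchical()` / `kmeans_cluster()` / `chi_square_association()` —
  sample and cohort stratification;
* `fit_cox()` / `apply_cox()` / `median_split()` / `km_curve()` /
  `logrank()` — multivariate Cox models on LSR features with Harrell's
  C, median-split risk groups and log-rank comparison;
* `binarize_ic50()` / `sr_drug_effect()` / `lsr_ratio()` /
  `ratio_ic50_correlation()` — drug-response analysis via the target's
  LSR share of SR;
* `simulate_ppi()` / `simulate_expression()` / `simulate_survival()` /
  `simulate_drug_panel()` — seeded synthetic data with planted ground
  truth for every stage;
* a thin command-line wrapper (`inst/scripts/sigentropy.R`) with
  subcommands `sr`, `dlsr`, `ora`, `cluster`, `survival`, `drug`,
  `simulate`, writing provenance-stamped TSV/JSON outputs.

## Worked example

A three-gene triangle network with a uniform "normal" sample and a
skewed "tumor" sample:

```r
library(sigentropy)

edges <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"))
class(edges) <- c("edge_list", "data.frame")
expr <- matrix(c(1, 1, 1,  1, 2, 3), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("normal1", "tumor1")))

net <- build_network(edges, expr)
#> build_network: 3 nodes / 3 edges in the largest connected component

em <- entropy_matrix(expr, net)
em$summary
#>    sample        sr    max_sr        SR
#> 1 normal1 0.6931472 0.6931472 1.0000000
#> 2  tumor1 0.6178349 0.6931472 0.8913473
round(em$lsr, 4)
#>   normal1 tumor1
#> A  0.3333 0.2207
#> B  0.3333 0.2950
#> C  0.3333 0.3757
```

The uniform profile on a regular graph attains the maximal-entropy walk
(SR = 1, each gene carrying an equal share); skewing expression toward
gene C drops SR to 0.891 and concentrates the local entropy on C. The
drug-target share of gene C — its LSR divided by total SR — is then

```r
lsr_ratio(em, data.frame(drug = "inhibitorX", target = "C"))
#>   cell_line       drug target     ratio
#> 1   normal1 inhibitorX      C 0.3333333
#> 2    tumor1 inhibitorX      C 0.4214592
```

i.e. gene C carries 42% of the tumor sample's signaling entropy, the
quantity correlated against ln-IC50 in the drug-response analysis.

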