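# cloneTree

Reconstruction of a tumor's subclonal phylogeny from multi-sample sequencing
data. Given variant/reference read counts — or pre-computed cellularity
estimates with standard errors — for mutations or mutation clusters across
several samples of one patient, `cloneTree` infers the rooted tree of
subclones that best explains how the tumor evolved.

The package is aimed at cancer-genomics analysts who already have somatic
calls (and optionally cluster assignments from tools such as PyClone or
SciClone) and want a principled, test-based ordering of subclones that is
decoupled from the cellularity-estimation step.

## Method in brief

For every ordered pair (i, j) of mutations or clusters, the null hypothesis
*"i can be an ancestor of j"* (cellularity of i ≥ cellularity of j in every
sample, by the lineage precedence rule) is tested with a generalized
likelihood ratio statistic

T = Σ_s (d̂_s / σ_s)² · 1(d̂_s < 0),

whose conservative null is a mixture of χ²_k distributions, k = 0…S, with
binomial weights C(S, k)/2^S. Rejections at a fixed α = 0.05 form the
precedence-order-violation (POV) matrix, aggregated over clusters into the
CPOV matrix. Candidate trees T are scored by

Z(T) = TC(T) + MC(T),  F(T) = exp(−f_c · Z(T)),  f_c = 5,

where the topology cost TC sums CPOV entries over the tree's transitive
(ancestor, descendant) pairs and the mass cost MC penalizes violations of the
lineage divergence rule (children's cellularities summing past their
parent's). A genetic algorithm (4 runs × 20 generations × 1000 trees, with
fitness-proportional selection, crossover and prune/swap mutations) searches
the n^(n−1) single-founder labeled topologies; small problems (n ≤ 7) can be
enumerated exhaustively instead. A built-in simulator generates datasets from
known trees (Dirichlet cellularity splits, Poisson depth, binomial reads) for
power and reconstruction benchmarks.

## Worked example

Cluster cellularities for four clusters in three samples, with standard
errors of 0.02:

```r
library(cloneTree)
V <- cbind(S1 = c(1.0, 0.55, 0.40, 0.40),
           S2 = c(1.0, 0.70, 0.60, 0.25),
           S3 = c(1.0, 0.30, 0.25, 0.65))
rownames(V) <- c("A", "B", "C", "D")
cm <- cellularity_matrix(V, matrix(0.02, 4, 3, dimnames = dimnames(V)))
fit <- fit_subclone_tree(cm, seed = 42,
                         control = ga_control(generation_size = 200,
                                              generations = 8, runs = 2))
summary(fit)
#> Subclone tree fit: 4 clusters, 3 samples
#> Topologies sampled: 64 | maximum-fitness set size: 1 | fitness: 1
#>
#> Edge support over the maximum-fitness set:
#>    parent child support
#>         A     B       1
#>         A     D       1
#>         B     C       1
#>  GERMLINE     A       1
#>
#> Subclone sizes (fraction of cancer cells) under the best tree:
#>     S1   S2   S3
#> A 0.05 0.05 0.05
#> B 0.15 0.10 0.05
#> C 0.40 0.60 0.25
#> D 0.40 0.25 0.65
```

The fit found a single maximum-fitness tree (fitness 1, so neither precedence
nor divergence evidence is violated): founder clone A with children B and D,
and C below B. Edge supports are the fraction of tied maximum-fitness trees
containing each edge — all 1 here because the optimum is unique. The subclone
sizes say, for instance, that in sample S2 60% of cancer cells belong to the
C subclone. `plot(fit)` draws the tree; `residuals(fit)` reports any
divergence violations per node and sample.

Mutation-level read counts take one extra step:

```r
rec <- read_mutation_table("mutations.tsv")      # per-mutation read counts
cm  <- mutation_cellularity_matrix(rec, purity = 0.9)  # naive estimator
pov <- build_pov(cm, alpha = 0.05)               # pairwise GLRT
cpov <- aggregate_cpov(pov, assignment)          # vote aggregation
res <- run_ga(cpov, cluster_mean_cellularity(cm, assignment), seed = 1)
```

The same pipeline is available from the shell via `exec/clonetree`
(subcommands `estimate`, `test`, `run-ga`, `sizes`, `simulate`, `benchmark`).

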