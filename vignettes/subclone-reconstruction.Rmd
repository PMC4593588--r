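---
title: "Reconstructing subclonal phylogenies from multi-sample tumor sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing subclonal phylogenies from multi-sample tumor sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneTree)
```

## The model

A tumor's somatic mutations accumulate along a rooted tree of subclones. Under
the infinite sites assumption, each mutation arises once and is inherited by
every descendant cell, so each mutation (or mutation cluster) is uniquely
assigned to one edge of the tree, and each non-root node is identified with the
cluster on its upstream edge. The root represents the germline state. Two
consequences of this model drive everything in `cloneTree`:

* **Lineage precedence** — an ancestral cluster's cellularity (the fraction of
  cancer cells carrying it) is at least its descendant's, in *every* sample
  from the patient.
* **Lineage divergence** — sibling subclones are disjoint cell populations, so
  the cellularities of a node's children can never sum to more than the node's
  own cellularity.

The package decouples cellularity estimation from tree inference: any
upstream tool's cluster cellularities (with standard errors) can be supplied,
or the built-in naive estimator can be used on raw read counts.

## The precedence hypothesis test

For an ordered pair (i, j), the null hypothesis is that *i can be an ancestor
of j*: the true cellularity differences `d_s = C_is - C_js` are non-negative
in all `S` samples. Estimated differences are modeled as independent normals
with known per-sample deviations (standard errors are plugged in). Maximizing
the likelihood over the one-sided parameter space yields the generalized
likelihood ratio statistic

$$T = \sum_{s=1}^{S}\left(\frac{\hat d_s}{\sigma_s}\right)^2
      \mathbb{1}(\hat d_s < 0),$$

the sum of squared z-scores over samples in which the ordering is observed
violated. Under the *reduced* null (all true differences zero) the statistic
is distributed as a mixture of chi-square distributions with `k = 0, ..., S`
degrees of freedom and binomial weights `choose(S, k) / 2^S` — conditioning on
which of the `S` independent z-scores land negative. Because the reduced null
is the least favorable point of the composite null, the resulting p-value is
conservative: with true margins `d_s > 0`, rejections become strictly rarer.
A fixed common per-test level `alpha = 0.05` is used with no multiplicity
correction; the matrix of rejections, not any single test, is the object of
interest downstream.

```{r}
# one clear reversal between two samples
ci <- list(value = c(0.3, 0.9), stderr = c(0.05, 0.05))
cj <- list(value = c(0.8, 0.2), stderr = c(0.05, 0.05))
test_precedence(ci, cj)
```

Rejections over all ordered pairs form the **POV matrix** (mutation level) or
**CPOV matrix** (cluster level). The CPOV can be obtained either by testing
cluster summaries directly (binary entries) or by *vote aggregation* of the
mutation-level POV: entry (I, J) is the fraction of rejecting member pairs,
a number in [0, 1]. The matrix diagonal is computed but never consulted by
tree scoring.

## Scoring and searching trees

A candidate topology `T` is scored by `Z(T) = TC(T) + MC(T)`:

* the **topology cost** sums CPOV entries over every *transitive*
  (ancestor, descendant) cluster pair of the tree — evidence against the
  lineage precedences the tree asserts;
* the **mass cost** penalizes divergence violations: per node and sample,
  the excess of the children's summed cellularity over the node's, combined
  across samples as a Euclidean norm and summed over nodes. The germline root
  carries implicit cellularity 1, so any founder cluster with cellularity at
  most 1 incurs no root cost.

Fitness is `F = exp(-f_c * Z)` with default scaling `f_c = 5`, making each
unit of cost shrink fitness by `exp(5) ≈ 148`, i.e. roughly 150-fold — small
enough to keep imperfect trees alive in the search, large enough that cost
differences dominate selection. A sensitivity check in the test suite
confirms `f_c = 5` recovers generating trees at least as often as 0.5 or 50.

The search space is all labeled rooted trees with a **single founder**
(exactly one germline child): every published subclone phylogeny we are aware
of has this form, and the random-topology generator only attaches new
clusters below existing non-root nodes. There are `n^(n-1)` such topologies
for `n` clusters; `enumerate_topologies()` handles `n <= 7`, beyond which the
genetic algorithm takes over.

The GA follows the classic schedule: 1000 random topologies per generation,
20 generations, 4 independent runs. Each generation is bred from 80%
roulette-selected parents (fitness-proportional, drawn from the *cumulative*
pool of all previous generations, deduplicated and capped at 50,000 entries)
plus 20% fresh random topologies. Selected pairs undergo crossover with
probability 0.25 and each child is mutated with probability 0.9.

The crossover and mutation operators are defined here as parent-map edits
that provably preserve the single-founder invariant:

* **crossover** picks a cluster that is a non-founder in both parents and
  transplants it onto the parent it has in the other tree; transplants that
  would create a cycle or a second founder are repaired by reattachment below
  a uniformly chosen non-descendant;
* **mutation** applies prune-and-regraft with probability 0.6, otherwise
  swaps the positions of two clusters.

Prune-and-regraft alone connects the whole topology space, so the search is
irreducible; correctness is anchored to an exhaustive-enumeration oracle in
the tests (for `n <= 5` the GA's maximum-fitness set must match enumeration's)
rather than to any particular operator scheme. Fitness ties are detected at a
relative tolerance of `1e-9` on canonical parent-map forms; roulette
probabilities are computed as `exp(-f_c (Z - Z_min))` so that large costs
cannot underflow to zero weight.

```{r}
tr <- subclone_tree(c(A = "GERMLINE", B = "A", C = "B", D = "A"))
V <- cbind(S1 = c(1.0, 0.55, 0.40, 0.40), S2 = c(1.0, 0.70, 0.60, 0.25),
           S3 = c(1.0, 0.30, 0.25, 0.65))
rownames(V) <- tr$clusters
cm <- cellularity_matrix(V, matrix(0.02, 4, 3, dimnames = dimnames(V)))
fit <- fit_subclone_tree(cm, seed = 42,
                         control = ga_control(generation_size = 200,
                                              generations = 8, runs = 2))
summary(fit)
```

Once a tree is chosen, the fraction of cancer cells in each subclone is the
cellularity a cluster keeps beyond its children's total
(`subclone_sizes()`); the sizes telescope to the founder's cellularity.

## Cellularity estimation

The naive estimator converts a variant allele fraction into cellularity under
a diploid-normal-contamination model,
`C = f * (CN * p + 2(1 - p)) / (m * p)`, supporting diploid (`CN = 2`) and
hemizygous (`CN = 1`) tumor regions with mutation multiplicity `m`; loci with
other copy numbers should be filtered out (`filter_mutations()`, which also
applies the conventional depth cut of 50 reads). Standard errors come from
the delta method on the binomial VAF variance, with two numerical guards:
the VAF is smoothed as `(v + 0.5)/(N + 1)` before the variance step so loci
observed at VAF 0 or 1 keep positive uncertainty, and the result is floored
at `1e-4` because the test statistic divides by it. Estimates are clamped to
[0, 1] with the raw value retained. Sample purity, when not supplied, is
estimated as twice the maximum cluster mean VAF (diploid founder assumption),
capped at 1. Published cluster mean VAFs can be converted directly via
`cluster_cellularity_from_vaf()`; it carries no standard error, which must
then come from published dispersions or the spread of member mutations
(`cluster_mean_cellularity()` combines member standard errors under
independence).

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the conditions used throughout the package's
benchmarks:

* topologies: exhaustive for 3–5 clusters, ten distinct uniform draws above;
* Poisson(10) mutations per edge, floored at one so every cluster remains
  observable;
* per sample, independently: the founder has cellularity 1 and each node's
  mass is divided among its children and a retained fraction by a symmetric
  Dirichlet(1) split — precedence and divergence hold *exactly* by
  construction, and the true tree always has zero mass cost;
* reads: depth Poisson at the nominal coverage (fixed-depth mode available),
  variant counts binomial at expected VAF `C * purity / 2` (diploid het).

The Dirichlet split was chosen as the simplest scheme satisfying the exact
lineage constraints while varying freely across samples. Real data differ in
ways deliberately not modeled: copy-number aberrations, clusters produced by
an upstream clustering tool (with its misassignments), spatially correlated
rather than independent samples, overdispersed read counts, and contamination
by normal subclones. Passing benchmarks therefore demonstrates correctness of
the inference machinery under the stated model, not robustness to those
artifacts.

Two behaviors of the scoring are worth knowing when reading benchmark output.
First, with very precise data the CPOV becomes effectively binary and several
topologies can tie at exactly zero cost whenever the data genuinely
underdetermine the tree (for example, a low-cellularity cluster that fits
under several parents without violating divergence); fractional vote-aggregated
CPOV entries, ironically, break such ties more often. The two-stage success
bookkeeping (`evaluate_ga()`) exists precisely to make this visible: Stage 1
asks whether at most two maximum-fitness trees remain, Stage 2 whether the
truth is among them. Second, for purely linear chains the topology cost alone
cannot separate the chain from the bushier arrangements consistent with the
same order, and the mass cost is what discriminates — when cellularities are
large enough that wrong attachments overflow their parent.

## Problem sizes and reproducibility

All randomness flows through R's generator: `run_ga(seed = )` derives one
seed per GA run, and the simulation helpers respect `set.seed()` directly.
The package's own validation uses reduced problem sizes chosen to exercise
every claim while keeping a full check run in minutes: null calibration on
10,000 simulated pairs at `S = 3`; power on node counts 3–8 with two
instances and five replicates each; GA-vs-enumeration on twenty seeded
instances at `n <= 5`; and reconstruction success on node counts 3–5 (at most
five instances, three replicates, sample count equal to node count) at the
two (purity, coverage) corners (0.5, 150X) and (0.9, 1000X). The
`scripts/acceptance.R` entry point reruns these end to end from a single
command-line seed.

## Known limitations

* Single-founder trees only; multi-founder (polyclonal origin) tumors are out
  of scope.
* Cellularity estimation ignores subclonal copy number; loci outside diploid
  or hemizygous regions must be filtered.
* The per-test level is not corrected for the number of pairs — by design,
  following the framework's fixed `alpha = 0.05` convention.
* No convergence criterion: the GA runs a fixed schedule, and on large trees
  (say 15 clusters) a run may need more generations than the default.
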