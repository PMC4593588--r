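#' Tree instances for a node count
#'
#' The benchmark's topology sets: exhaustive enumeration for 3-5 clusters,
#' otherwise 10 distinct uniformly sampled topologies.
#'
#' @param node_count number of clusters (>= 3 for benchmark use).
#' @param n_random how many distinct topologies to sample when the node
#'   count exceeds the exhaustive range (default 10).
#' @return list of `subclone_tree` objects with labels `C1..Cn`.
#' @export
tree_instances <- function(node_count, n_random = 10L) {
  if (node_count < 3L) stop("benchmark trees have at least 3 nodes", call. = FALSE)
  clusters <- paste0("C", seq_len(node_count))
  if (node_count <= 5L) return(enumerate_topologies(clusters))
  out <- list()
  seen <- character()
  while (length(out) < n_random) {
    t <- random_topology(clusters)
    k <- canonical_form(t)
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      out[[length(out) + 1L]] <- t
    }
  }
  out
}

#' Assign simulated mutations to tree edges
#'
#' Per-edge mutation counts are Poisson(`lambda`), floored at 1 so every
#' cluster remains observable.
#'
#' @param tree a `subclone_tree`.
#' @param lambda Poisson mean mutations per edge (default 10).
#' @return named character vector mapping mutation id (`M1, M2, ...`) to
#'   cluster id.
#' @export
assign_mutations <- function(tree, lambda = 10) {
  if (lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  counts <- pmax(1L, stats::rpois(length(tree$clusters), lambda))
  cl <- rep(tree$clusters, counts)
  stats::setNames(cl, paste0("M", seq_along(cl)))
}

#' Simulate true cluster cellularities consistent with a tree
#'
#' Each sample is an independent instantiation of cellularity over the
#' edges: the founder clone has cellularity 1 (every cancer cell carries the
#' founder mutations), and at each node the parent's cellularity is divided
#' among its children and a retained fraction by a symmetric Dirichlet(1)
#' split. By construction the lineage precedence and divergence rules hold
#' exactly in every sample.
#'
#' @param tree a `subclone_tree`.
#' @param n_samples number of samples S.
#' @return numeric matrix (clusters x samples, samples named `S1..S`).
#' @export
simulate_cellularities <- function(tree, n_samples) {
  if (n_samples < 1L) stop("need at least one sample", call. = FALSE)
  p <- tree_to_idx(tree)
  n <- length(p)
  # topological order: parents before children
  depth <- integer(n)
  for (j in seq_len(n)) {
    a <- p[j]
    while (a != 0L) { depth[j] <- depth[j] + 1L; a <- p[a] }
  }
  ord <- order(depth)
  C <- matrix(NA_real_, n, n_samples,
              dimnames = list(tree$clusters, paste0("S", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    val <- numeric(n)
    val[p == 0L] <- 1
    for (i in ord) {
      kids <- which(p == i)
      if (!length(kids)) next
      w <- stats::rexp(length(kids) + 1L)
      w <- w / sum(w)
      val[kids] <- val[i] * w[seq_along(kids)]
    }
    C[, s] <- val
  }
  C
}

#' Simulate read counts for assigned mutations
#'
#' Per mutation and sample, sequencing depth is Poisson(`coverage`) (or
#' fixed at `coverage` when `fixed_depth = TRUE`) and the variant count is
#' binomial with success probability `cellularity * purity / 2`, the
#' expected VAF of a diploid heterozygous mutation.
#'
#' @param cellularity true cluster cellularity matrix (clusters x samples).
#' @param assignment named map mutation id -> cluster id.
#' @param purity tumor purity in (0, 1].
#' @param coverage mean sequencing depth.
#' @param fixed_depth use exactly `coverage` reads per locus.
#' @return mutation-table data.frame (`mutation_id`, `sample_id`,
#'   `ref_count`, `var_count`, `copy_number`, `multiplicity`, `cluster_id`).
#' @export
simulate_reads <- function(cellularity, assignment, purity, coverage,
                           fixed_depth = FALSE) {
  if (purity <= 0 || purity > 1) stop("'purity' must be in (0, 1]", call. = FALSE)
  if (coverage <= 0) stop("'coverage' must be positive", call. = FALSE)
  muts <- names(assignment)
  samples <- colnames(cellularity)
  m <- length(muts)
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    depth <- if (fixed_depth) rep(as.integer(round(coverage)), m) else
      stats::rpois(m, coverage)
    vaf <- cellularity[assignment[muts], s] * purity / 2
    var_count <- stats::rbinom(m, depth, vaf)
    out[[k]] <- data.frame(mutation_id = muts, sample_id = s,
                           ref_count = depth - var_count,
                           var_count = var_count,
                           copy_number = 2L, multiplicity = 1L,
                           cluster_id = unname(assignment[muts]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cluster-level precedence truth table of a tree
#'
#' Entry (I, J) is 0 when I is an ancestor of J or I equals J (precedence
#' cannot be rejected), 1 otherwise.
#'
#' @param tree a `subclone_tree`.
#' @return binary integer matrix with cluster dimnames.
#' @export
truth_pov <- function(tree) {
  A <- ancestor_matrix(tree)
  truth <- 1L - (A | diag(TRUE, nrow(A)))
  storage.mode(truth) <- "integer"
  truth
}

#' Simulate a complete multi-sample dataset from a known tree
#'
#' @param tree the generating `subclone_tree`.
#' @param n_samples number of tumor samples.
#' @param purity tumor purity shared by all samples.
#' @param coverage mean sequencing depth.
#' @param lambda Poisson mean mutations per edge.
#' @param fixed_depth see [simulate_reads()].
#' @return object of class `sim_dataset`: `true_tree`, `cellularity` (true
#'   cluster x sample values), `assignment`, `reads`, `truth_pov`, `purity`,
#'   `coverage`.
#' @export
simulate_dataset <- function(tree, n_samples, purity = 0.9, coverage = 1000,
                             lambda = 10, fixed_depth = FALSE) {
  assignment <- assign_mutations(tree, lambda)
  cellularity <- simulate_cellularities(tree, n_samples)
  reads <- simulate_reads(cellularity, assignment, purity, coverage,
                          fixed_depth)
  structure(list(true_tree = tree, cellularity = cellularity,
                 assignment = assignment, reads = reads,
                 truth_pov = truth_pov(tree),
                 purity = purity, coverage = coverage),
            class = "sim_dataset")
}

#' Power and Type 1 error of a POV matrix against the generating tree
#'
#' Each POV entry is compared to its truth under the generating topology:
#' entry (i, j) should be 0 when cluster(i) is an ancestor of or equal to
#' cluster(j), 1 otherwise. Power is the detection rate over truth-1
#' entries; Type 1 error is the rejection rate over off-diagonal truth-0
#' entries.
#'
#' @param pov binary POV matrix over the dataset's mutations (or clusters).
#' @param dataset a `sim_dataset`.
#' @return list with `power`, `type1_error` and the entry counts
#'   `n_truth1`, `n_truth0`.
#' @export
evaluate_pov <- function(pov, dataset) {
  ids <- rownames(pov)
  cl_truth <- dataset$truth_pov
  if (all(ids %in% names(dataset$assignment))) {
    cl <- dataset$assignment[ids]
  } else if (all(ids %in% rownames(cl_truth))) {
    cl <- stats::setNames(ids, ids)
  } else {
    stop("POV ids do not match the dataset's mutations or clusters",
         call. = FALSE)
  }
  truth <- cl_truth[cl, cl, drop = FALSE]
  off <- !diag(TRUE, nrow(pov))
  t1 <- truth == 1L & off
  t0 <- truth == 0L & off
  list(power = if (any(t1)) mean(pov[t1]) else NA_real_,
       type1_error = if (any(t0)) mean(pov[t0]) else NA_real_,
       n_truth1 = sum(t1), n_truth0 = sum(t0))
}

#' Stage-1 / Stage-2 success of a GA reconstruction
#'
#' Stage 1 succeeds when at most two maximum-fitness trees are returned;
#' Stage 2 (defined only given Stage-1 success) when the true tree is among
#' them.
#'
#' @param result a `ga_result`.
#' @param true_tree the generating `subclone_tree`.
#' @return list with logicals `stage1` and `stage2` (`NA` when Stage 1
#'   fails) and `n_max_fitness`.
#' @export
evaluate_ga <- function(result, true_tree) {
  mfs <- result$max_fitness_set
  stage1 <- length(mfs) <= 2L
  key <- canonical_form(true_tree)
  stage2 <- if (!stage1) NA else
    key %in% vapply(mfs, canonical_form, "")
  list(stage1 = stage1, stage2 = stage2, n_max_fitness = length(mfs))
}

# full estimate -> test pipeline for one simulated dataset
pov_from_dataset <- function(dataset, alpha = 0.05) {
  cm <- mutation_cellularity_matrix(dataset$reads, dataset$purity)
  build_pov(cm, alpha)
}

#' Benchmark grid over purity, coverage, tree size and sample count
#'
#' For every grid cell, simulates tree instances and replicates, estimates
#' mutation cellularities with the naive estimator, builds the POV matrix
#' and scores power / Type 1 error against the topology truth; optionally
#' also runs the GA on the vote-aggregated CPOV and cluster mean
#' cellularities and records Stage-1 / Stage-2 success.
#'
#' @param node_counts tree sizes to simulate.
#' @param sample_counts samples per simulated patient.
#' @param purity,coverage vectors of purity and mean depth settings.
#' @param instances_per_count cap on topology instances per node count.
#' @param replicates replicates per instance (independent cellularity and
#'   read draws).
#' @param alpha per-test significance level.
#' @param lambda Poisson mean mutations per edge.
#' @param ga run the genetic algorithm per replicate (expensive).
#' @param control [ga_control()] used when `ga = TRUE`.
#' @param noiseless score the POV on true cluster cellularities with a tiny
#'   standard error instead of read-based estimates (no-noise limit).
#' @param seed optional master seed.
#' @return data.frame, one row per (purity, coverage, node count, sample
#'   count) cell: mean `power` and `type1_error` with standard errors over
#'   replicates, and when `ga = TRUE` the `stage1` fraction, conditional
#'   `stage2` fraction and joint `ga_success` fraction.
#' @export
run_benchmark <- function(node_counts = 3:8, sample_counts = c(1, 3, 5, 10),
                          purity = c(0.5, 0.9), coverage = c(150, 1000),
                          instances_per_count = Inf, replicates = 10L,
                          alpha = 0.05, lambda = 10,
                          ga = FALSE, control = ga_control(),
                          noiseless = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  instances <- lapply(node_counts, function(n) {
    inst <- tree_instances(n)
    if (length(inst) > instances_per_count) {
      inst <- inst[sample.int(length(inst), instances_per_count)]
    }
    inst
  })
  names(instances) <- as.character(node_counts)
  grid <- expand.grid(purity = purity, coverage = coverage,
                      node_count = node_counts, sample_count = sample_counts,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pw <- c(); t1 <- c(); s1 <- c(); s2 <- c(); joint <- c()
    for (tree in instances[[as.character(grid$node_count[g])]]) {
      for (r in seq_len(replicates)) {
        ds <- simulate_dataset(tree, grid$sample_count[g], grid$purity[g],
                               grid$coverage[g], lambda)
        if (noiseless) {
          cm <- cellularity_matrix(ds$cellularity,
                                   matrix(1e-4, nrow(ds$cellularity),
                                          ncol(ds$cellularity)))
          ev <- evaluate_pov(build_pov(cm, alpha), ds)
          pov <- NULL
        } else {
          pov <- pov_from_dataset(ds, alpha)
          ev <- evaluate_pov(pov, ds)
        }
        pw <- c(pw, ev$power); t1 <- c(t1, ev$type1_error)
        if (ga) {
          if (is.null(pov)) pov <- pov_from_dataset(ds, alpha)
          cm_mut <- mutation_cellularity_matrix(ds$reads, ds$purity)
          cpov <- aggregate_cpov(pov, ds$assignment)
          ccell <- cluster_mean_cellularity(cm_mut, ds$assignment)
          res <- run_ga(cpov, ccell$value, control,
                        seed = sample.int(.Machine$integer.max, 1L))
          evg <- evaluate_ga(res, tree)
          s1 <- c(s1, evg$stage1)
          if (evg$stage1) s2 <- c(s2, evg$stage2)
          joint <- c(joint, evg$stage1 && isTRUE(evg$stage2))
        }
      }
    }
    row <- data.frame(grid[g, , drop = FALSE],
                      power = mean(pw, na.rm = TRUE),
                      power_se = stats::sd(pw, na.rm = TRUE) /
                        sqrt(sum(!is.na(pw))),
                      type1_error = mean(t1, na.rm = TRUE),
                      type1_se = stats::sd(t1, na.rm = TRUE) /
                        sqrt(sum(!is.na(t1))),
                      n_replicates = length(pw))
    if (ga) {
      row$stage1 <- mean(s1)
      row$stage2 <- if (length(s2)) mean(s2) else NA_real_
      row$ga_success <- mean(joint)
    }
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
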