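#' Genetic-algorithm control parameters
#'
#' Defaults follow the published search schedule: 1000 trees per generation,
#' 20 generations, 4 independent runs, crossover probability 0.25, mutation
#' probability 0.9, operator choice probability 0.6 (prune-and-regraft vs
#' label swap), 80% of each new generation bred from roulette-selected
#' parents and 20% fresh random topologies, fitness scaling 5.
#'
#' @param generation_size trees per generation (G0).
#' @param generations number of generations per run.
#' @param runs independent GA runs whose ensembles are merged.
#' @param crossover_prob probability a selected pair undergoes crossover.
#' @param mutation_prob probability each progeny tree is mutated.
#' @param operator_choice_prob probability the mutation operator is
#'   prune-and-regraft rather than a label swap.
#' @param selection_fraction fraction of each generation bred from selected
#'   parents; `selection_fraction + random_fraction` must equal 1.
#' @param random_fraction fraction of fresh random topologies per generation.
#' @param fitness_scaling cost-to-fitness scaling coefficient `f_c`.
#' @param pool_cap maximum number of distinct topologies kept in the
#'   cumulative parent pool (highest fitness kept).
#' @param max_fitness_tol relative fitness tolerance for tie detection in the
#'   maximum-fitness set.
#' @return a `ga_control` list.
#' @export
ga_control <- function(generation_size = 1000L, generations = 20L, runs = 4L,
                       crossover_prob = 0.25, mutation_prob = 0.9,
                       operator_choice_prob = 0.6,
                       selection_fraction = 0.8, random_fraction = 0.2,
                       fitness_scaling = 5, pool_cap = 50000L,
                       max_fitness_tol = 1e-9) {
  ctrl <- list(generation_size = as.integer(generation_size),
               generations = as.integer(generations), runs = as.integer(runs),
               crossover_prob = crossover_prob, mutation_prob = mutation_prob,
               operator_choice_prob = operator_choice_prob,
               selection_fraction = selection_fraction,
               random_fraction = random_fraction,
               fitness_scaling = fitness_scaling,
               pool_cap = as.integer(pool_cap),
               max_fitness_tol = max_fitness_tol)
  probs <- c(crossover_prob, mutation_prob, operator_choice_prob,
             selection_fraction, random_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(selection_fraction + random_fraction - 1) > 1e-12) {
    stop("selection_fraction + random_fraction must equal 1", call. = FALSE)
  }
  if (ctrl$generation_size < 2L || ctrl$generations < 1L || ctrl$runs < 1L ||
      fitness_scaling <= 0) {
    stop("invalid GA configuration", call. = FALSE)
  }
  class(ctrl) <- "ga_control"
  ctrl
}

#' Fitness-proportional (roulette) parent selection
#'
#' @param trees list of `subclone_tree` candidates.
#' @param fitness positive fitness of each candidate.
#' @param count number of parents to draw (with replacement).
#' @return list of selected trees.
#' @export
select_parents <- function(trees, fitness, count) {
  if (!length(trees)) stop("empty candidate pool", call. = FALSE)
  if (length(fitness) != length(trees) || any(fitness <= 0)) {
    stop("'fitness' must be positive, one value per tree", call. = FALSE)
  }
  idx <- sample.int(length(trees), count, replace = TRUE, prob = fitness)
  trees[idx]
}

# ---- operators on the integer encoding ------------------------------------

# Move cluster c below newpar (index, 0 = germline); repair infeasible moves
# by reattaching below a uniformly chosen non-descendant cluster. The founder
# is never moved (only the no-op transplant onto the root is feasible).
idx_transplant <- function(p, c, newpar) {
  if (newpar == p[c]) return(p)
  if (p[c] == 0L) return(p)            # founder stays the single germline child
  feasible <- newpar != 0L && newpar != c &&
    !(newpar %in% idx_descendants(p, c))
  if (!feasible) {
    cand <- setdiff(seq_along(p), c(c, idx_descendants(p, c)))
    newpar <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }
  p[c] <- newpar
  p
}

idx_crossover <- function(pa, pb) {
  n <- length(pa)
  nonf <- which(pa != 0L & pb != 0L)
  c <- if (!length(nonf)) sample.int(n, 1L) else
    if (length(nonf) == 1L) nonf else nonf[sample.int(length(nonf), 1L)]
  list(idx_transplant(pa, c, pb[c]), idx_transplant(pb, c, pa[c]))
}

idx_mutate <- function(p, p_s) {
  n <- length(p)
  if (n < 2L) return(p)
  if (stats::runif(1) < p_s) {
    op <- "regraft"
    nonf <- which(p != 0L)
    c <- if (length(nonf) == 1L) nonf else nonf[sample.int(length(nonf), 1L)]
    cand <- setdiff(seq_len(n), c(c, idx_descendants(p, c)))
    p[c] <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  } else {
    op <- "swap"
    sw <- sample.int(n, 2L)
    perm <- seq_len(n)
    perm[sw] <- rev(sw)
    relab <- p
    nz <- p != 0L
    relab[nz] <- perm[p[nz]]
    q <- p
    q[perm] <- relab
    p <- q
  }
  attr(p, "op") <- op
  p
}

#' Crossover operator on a pair of trees
#'
#' Picks one cluster (uniformly among clusters that are non-founder in both
#' parents) and transplants it onto the parent it has in the other tree.
#' Transplants that would create a cycle or a second founder are repaired by
#' reattachment below a uniformly chosen non-descendant cluster, so both
#' children always satisfy the tree invariants.
#'
#' @param a,b `subclone_tree` objects over the same cluster set.
#' @return list of two `subclone_tree` children.
#' @export
crossover_trees <- function(a, b) {
  if (!setequal(a$clusters, b$clusters)) {
    stop("trees must share the same cluster set", call. = FALSE)
  }
  cl <- a$clusters
  kids <- idx_crossover(tree_to_idx(a), tree_to_idx(b, cl))
  lapply(kids, idx_to_tree, clusters = cl)
}

#' Mutation operator on a tree
#'
#' With probability `p_s` applies prune-and-regraft (a random non-founder
#' cluster is reattached below a uniformly chosen non-descendant node),
#' otherwise swaps the positions of two distinct clusters. Single-cluster
#' trees are returned unchanged.
#'
#' @param tree a `subclone_tree`.
#' @param p_s probability of choosing prune-and-regraft over label swap.
#' @return a valid `subclone_tree`; the operator applied is recorded in
#'   attribute `"op"`.
#' @export
mutate_tree <- function(tree, p_s = 0.6) {
  p <- idx_mutate(tree_to_idx(tree), p_s)
  out <- idx_to_tree(as.integer(p), tree$clusters)
  attr(out, "op") <- attr(p, "op")
  out
}

# ---- GA driver ------------------------------------------------------------

# One GA run. cpov/cell are matrices aligned to `clusters` order (cell may be
# NULL). Returns the deduplicated pool with costs and the best-fitness trace.
run_one_ga <- function(clusters, cpov, cell, ctrl) {
  n <- length(clusters)
  G0 <- ctrl$generation_size
  nsel <- round(ctrl$selection_fraction * G0)
  nrand <- G0 - nsel
  fc <- ctrl$fitness_scaling

  cache <- new.env(hash = TRUE, parent = emptyenv())
  cost_of <- function(P, keys) {
    z <- numeric(nrow(P))
    for (r in seq_len(nrow(P))) {
      k <- keys[r]
      v <- cache[[k]]
      if (is.null(v)) {
        v <- score_idx(P[r, ], cpov, cell, fc)$total_cost
        cache[[k]] <- v
      }
      z[r] <- v
    }
    z
  }
  key_of <- function(P) apply(P, 1L, paste, collapse = ",")

  pool_P <- NULL; pool_key <- character(); pool_Z <- numeric()
  add_pool <- function(P, keys, z) {
    fresh <- !duplicated(keys) & !(keys %in% pool_key)
    if (any(fresh)) {
      pool_P <<- rbind(pool_P, P[fresh, , drop = FALSE])
      pool_key <<- c(pool_key, keys[fresh])
      pool_Z <<- c(pool_Z, z[fresh])
      if (length(pool_key) > ctrl$pool_cap) {
        keep <- order(pool_Z)[seq_len(ctrl$pool_cap)]
        pool_P <<- pool_P[keep, , drop = FALSE]
        pool_key <<- pool_key[keep]
        pool_Z <<- pool_Z[keep]
      }
    }
  }

  trace <- numeric(ctrl$generations + 1L)
  P <- random_topology_batch(n, G0)
  keys <- key_of(P)
  add_pool(P, keys, cost_of(P, keys))
  trace[1L] <- exp(-fc * min(pool_Z))

  for (g in seq_len(ctrl$generations)) {
    # roulette over the cumulative pool; probabilities shifted to avoid
    # underflow of exp(-fc * Z) at large costs
    prob <- exp(-fc * (pool_Z - min(pool_Z)))
    sel <- sample.int(length(pool_key), nsel, replace = TRUE, prob = prob)
    prog <- matrix(0L, nsel, n)
    i <- 1L
    while (i <= nsel) {
      if (i == nsel) {                       # odd leftover passes through
        child <- pool_P[sel[i], ]
        if (stats::runif(1) < ctrl$mutation_prob) {
          child <- as.integer(idx_mutate(child, ctrl$operator_choice_prob))
        }
        prog[i, ] <- child
        i <- i + 1L
      } else {
        pa <- pool_P[sel[i], ]; pb <- pool_P[sel[i + 1L], ]
        kids <- if (stats::runif(1) < ctrl$crossover_prob) {
          idx_crossover(pa, pb)
        } else list(pa, pb)
        for (j in 1:2) {
          child <- kids[[j]]
          if (stats::runif(1) < ctrl$mutation_prob) {
            child <- as.integer(idx_mutate(child, ctrl$operator_choice_prob))
          }
          prog[i + j - 1L, ] <- child
        }
        i <- i + 2L
      }
    }
    P <- rbind(prog, random_topology_batch(n, nrand))
    keys <- key_of(P)
    add_pool(P, keys, cost_of(P, keys))
    trace[g + 1L] <- exp(-fc * min(pool_Z))
  }
  list(P = pool_P, key = pool_key, Z = pool_Z, trace = trace)
}

#' Genetic-algorithm search for maximum-fitness subclone trees
#'
#' Runs several independent GA searches over single-founder labeled tree
#' topologies, scoring each candidate by [tree_fitness()] against the CPOV
#' matrix and (optionally) cluster cellularities. Each run starts from
#' random topologies, breeds each generation from a cumulative
#' fitness-proportional parent pool via crossover and mutation, and tops up
#' with fresh random trees; the ensembles of all runs are merged,
#' deduplicated by canonical form, and ranked by fitness.
#'
#' @param cpov square CPOV matrix with cluster dimnames, or `NULL` to score
#'   by mass cost alone.
#' @param cellularity cluster-level [cellularity_matrix()] or numeric value
#'   matrix, or `NULL` to score by topology cost alone.
#' @param control a [ga_control()] list.
#' @param seed optional integer; per-run seeds are derived from it.
#' @return object of class `ga_result`: `ensemble` (data.frame of distinct
#'   topologies with costs and fitness, best first), `trees` (matching list
#'   of `subclone_tree`s), `max_fitness_set`, `max_fitness` /
#'   `max_fitness_score`, `traces` (runs x generations+1 best-so-far
#'   fitness), `clusters`, `control`, `seed`.
#' @export
run_ga <- function(cpov, cellularity = NULL, control = ga_control(),
                   seed = NULL) {
  if (!inherits(control, "ga_control")) {
    stop("'control' must come from ga_control()", call. = FALSE)
  }
  if (is.null(cpov) && is.null(cellularity)) {
    stop("need at least one of 'cpov' and 'cellularity'", call. = FALSE)
  }
  clusters <- if (!is.null(cpov)) rownames(cpov) else {
    if (inherits(cellularity, "cellularity_matrix")) rownames(cellularity$value)
    else rownames(cellularity)
  }
  if (is.null(clusters)) stop("inputs must carry cluster dimnames", call. = FALSE)
  ref <- idx_to_tree(c(0L, rep(1L, length(clusters) - 1L)), clusters)
  cpov_al <- if (is.null(cpov)) NULL else align_cpov(ref, cpov)
  cell_al <- if (is.null(cellularity)) NULL else align_cell(ref, cellularity)
  if (!is.null(cpov_al) && !is.null(cell_al) &&
      !setequal(rownames(cpov_al), rownames(cell_al))) {
    stop("'cpov' and 'cellularity' must cover the same clusters", call. = FALSE)
  }

  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, control$runs)

  all_P <- NULL; all_key <- character(); all_Z <- numeric()
  traces <- matrix(NA_real_, control$runs, control$generations + 1L)
  for (r in seq_len(control$runs)) {
    set.seed(run_seeds[r])
    res <- run_one_ga(clusters, cpov_al, cell_al, control)
    fresh <- !(res$key %in% all_key)
    all_P <- rbind(all_P, res$P[fresh, , drop = FALSE])
    all_key <- c(all_key, res$key[fresh])
    all_Z <- c(all_Z, res$Z[fresh])
    traces[r, ] <- res$trace
  }
  o <- order(all_Z)
  all_P <- all_P[o, , drop = FALSE]
  all_Z <- all_Z[o]
  fc <- control$fitness_scaling
  fit <- exp(-fc * all_Z)
  trees <- lapply(seq_len(nrow(all_P)),
                  function(r) idx_to_tree(all_P[r, ], clusters))
  scores <- lapply(seq_len(nrow(all_P)), function(r)
    score_idx(all_P[r, ], cpov_al, cell_al, fc))
  ensemble <- data.frame(
    rank = seq_along(all_Z),
    topology = vapply(trees, canonical_form, ""),
    topology_cost = vapply(scores, `[[`, 0, "topology_cost"),
    mass_cost = vapply(scores, `[[`, 0, "mass_cost"),
    total_cost = all_Z,
    fitness = fit,
    stringsAsFactors = FALSE)
  in_max <- fit >= (1 - control$max_fitness_tol) * fit[1L]
  structure(list(ensemble = ensemble, trees = trees,
                 max_fitness_set = trees[in_max],
                 max_fitness = fit[1L],
                 max_fitness_score = scores[[1L]],
                 traces = traces, clusters = clusters,
                 control = control, seed = seed),
            class = "ga_result")
}

#' Extract the maximum-fitness set from a GA result
#'
#' @param result a `ga_result`.
#' @param rel_tol relative fitness tolerance for ties (default from the
#'   result's control).
#' @return list of `subclone_tree` objects within tolerance of the best
#'   fitness.
#' @export
maximum_fitness_set <- function(result, rel_tol = NULL) {
  if (!inherits(result, "ga_result")) stop("not a ga_result", call. = FALSE)
  if (is.null(rel_tol)) rel_tol <- result$control$max_fitness_tol
  fit <- result$ensemble$fitness
  result$trees[fit >= (1 - rel_tol) * fit[1L]]
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA search over", length(x$clusters), "clusters:",
      nrow(x$ensemble), "distinct topologies sampled in",
      x$control$runs, "run(s)\n")
  cat("Maximum fitness", format(x$max_fitness, digits = 6),
      "attained by", length(x$max_fitness_set), "topology(ies)\n")
  print(x$max_fitness_set[[1L]])
  invisible(x)
}
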