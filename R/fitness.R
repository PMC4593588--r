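#' Tree costs and fitness
#'
#' A candidate subclone tree is scored by two costs. The *topology cost*
#' charges, for every ordered (ancestor, descendant) cluster pair in the
#' tree (ancestry taken transitively), the corresponding CPOV entry — the
#' evidence against that precedence from the hypothesis tests. The *mass
#' cost* charges violations of the lineage divergence rule: for each node,
#' per sample, the amount by which its children's summed cellularity exceeds
#' its own, combined across samples as a Euclidean norm and summed over
#' nodes. The germline root participates with implicit cellularity 1 in
#' every sample, so a founder clone with cellularity at most 1 incurs no
#' root mass cost. Fitness maps total cost Z through `exp(-f_c * Z)`; with
#' the default scaling `f_c = 5` each unit of cost reduces fitness about
#' 150-fold.
#'
#' @name tree-fitness
NULL

# Core scorer on the integer encoding. `cell` may be NULL (mass cost
# disabled, e.g. to study the topology cost alone). Returns per-node mass
# detail when detail = TRUE.
score_idx <- function(parent_idx, cpov, cell, fc = 5, detail = FALSE) {
  n <- length(parent_idx)
  TC <- 0
  if (!is.null(cpov)) {
    for (j in seq_len(n)) {
      a <- parent_idx[j]
      while (a != 0L) {
        TC <- TC + cpov[a, j]
        a <- parent_idx[a]
      }
    }
  }
  MC <- 0
  mc_node <- NULL
  mc_sample <- NULL
  if (!is.null(cell)) {
    S <- ncol(cell)
    mc_node <- numeric(n + 1L)
    mc_sample <- matrix(0, n + 1L, S)
    for (i in 0:n) {
      kids <- which(parent_idx == i)
      if (!length(kids)) next
      ksum <- if (length(kids) == 1L) cell[kids, ] else
        colSums(cell[kids, , drop = FALSE])
      pc <- if (i == 0L) rep(1, S) else cell[i, ]
      ex <- pmax(0, ksum - pc)
      mc_sample[i + 1L, ] <- ex
      mc_node[i + 1L] <- sqrt(sum(ex * ex))
    }
    MC <- sum(mc_node)
  }
  Z <- TC + MC
  out <- list(topology_cost = TC, mass_cost = MC, total_cost = Z,
              fitness = exp(-fc * Z), scaling = fc)
  if (detail) {
    out$node_mass_cost <- mc_node
    out$sample_mass_cost <- mc_sample
  }
  out
}

# Align a cluster-named square matrix / cellularity input to tree order.
align_cpov <- function(tree, cpov) {
  cl <- tree$clusters
  if (is.null(rownames(cpov)) ||
      !setequal(rownames(cpov), cl) || !setequal(colnames(cpov), cl)) {
    stop("CPOV matrix must cover exactly the tree's clusters", call. = FALSE)
  }
  cpov[cl, cl, drop = FALSE]
}

align_cell <- function(tree, cellularity) {
  V <- if (inherits(cellularity, "cellularity_matrix")) cellularity$value
       else as.matrix(cellularity)
  cl <- tree$clusters
  if (is.null(rownames(V)) || !all(cl %in% rownames(V))) {
    stop("cellularity values missing for some clusters", call. = FALSE)
  }
  if (anyNA(V)) stop("cellularity values must be complete", call. = FALSE)
  V[cl, , drop = FALSE]
}

#' @describeIn tree-fitness topology cost: sum of CPOV entries over all
#'   transitive (ancestor, descendant) cluster pairs of the tree.
#' @param tree a `subclone_tree`.
#' @param cpov square CPOV matrix with cluster dimnames (binary or
#'   vote-aggregated fractions).
#' @export
topology_cost <- function(tree, cpov) {
  score_idx(tree_to_idx(tree), align_cpov(tree, cpov), NULL)$topology_cost
}

#' @describeIn tree-fitness mass cost with per-node detail (`node` names the
#'   germline root `"GERMLINE"`).
#' @param cellularity cluster-level [cellularity_matrix()] or plain numeric
#'   matrix of cellularity values (clusters x samples).
#' @export
mass_cost <- function(tree, cellularity) {
  sc <- score_idx(tree_to_idx(tree), NULL, align_cell(tree, cellularity),
                  detail = TRUE)
  structure(sc$mass_cost,
            node_mass_cost = stats::setNames(sc$node_mass_cost,
                                             c(GERMLINE, tree$clusters)),
            sample_mass_cost = sc$sample_mass_cost)
}

#' @describeIn tree-fitness full score: topology cost, mass cost, total cost
#'   and fitness `exp(-f_c * Z)`, returned as a `tree_score` object. Either
#'   cost term can be disabled by passing `NULL` for its input.
#' @param fc positive scaling coefficient (default 5).
#' @export
tree_fitness <- function(tree, cpov, cellularity, fc = 5) {
  if (length(fc) != 1L || fc <= 0) stop("'fc' must be positive", call. = FALSE)
  sc <- score_idx(tree_to_idx(tree),
                  if (is.null(cpov)) NULL else align_cpov(tree, cpov),
                  if (is.null(cellularity)) NULL else align_cell(tree, cellularity),
                  fc = fc)
  class(sc) <- "tree_score"
  sc
}

#' @export
print.tree_score <- function(x, ...) {
  cat("Tree score: TC =", format(x$topology_cost, digits = 6),
      " MC =", format(x$mass_cost, digits = 6),
      " Z =", format(x$total_cost, digits = 6),
      " F =", format(x$fitness, digits = 6), "\n")
  invisible(x)
}

#' Fitness implied by a total cost
#'
#' @param Z total cost (non-negative).
#' @param fc scaling coefficient (default 5).
#' @return `exp(-fc * Z)`.
#' @export
cost_to_fitness <- function(Z, fc = 5) exp(-fc * Z)

#' Subclone sizes under a tree
#'
#' The fraction of cancer cells belonging to each subclone: a node keeps
#' whatever cellularity its cluster has beyond the total claimed by its
#' children, `size_s(n) = C_n_s - sum(children C)`. Leaves keep their full
#' cluster cellularity and the sizes telescope to the founder's cellularity.
#' Small violations of lineage divergence in estimated data can turn sizes
#' negative; these are clamped to 0 with a warning.
#'
#' @param tree a `subclone_tree`.
#' @param cellularity cluster-level [cellularity_matrix()] or numeric matrix.
#' @return numeric matrix (clusters x samples) of subclone size fractions.
#' @export
subclone_sizes <- function(tree, cellularity) {
  V <- align_cell(tree, cellularity)
  p <- tree_to_idx(tree)
  n <- length(p)
  sizes <- V
  for (i in seq_len(n)) {
    kids <- which(p == i)
    if (length(kids)) {
      sizes[i, ] <- V[i, ] - colSums(V[kids, , drop = FALSE])
    }
  }
  if (any(sizes < 0)) {
    warning("lineage divergence violated: ", sum(sizes < 0),
            " negative subclone size(s) clamped to 0", call. = FALSE)
    sizes[sizes < 0] <- 0
  }
  sizes
}
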