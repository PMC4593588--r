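#' Fit a subclone tree to multi-sample cellularity estimates
#'
#' The main entry point of the package: given cluster-level cellularity
#' estimates (values and standard errors) across samples of one patient, it
#' (1) runs the pairwise lineage-precedence test at level `alpha` to build
#' the CPOV matrix, and (2) searches labeled single-founder tree topologies
#' with the genetic algorithm, scoring each candidate by the combined
#' topology and mass cost. The result is the maximum-fitness tree together
#' with any ties, edge supports across the tied set, and subclone size
#' estimates under the best tree.
#'
#' @param cellularity cluster-level [cellularity_matrix()] (clusters x
#'   samples, with standard errors).
#' @param cpov optional precomputed CPOV matrix (e.g. vote-aggregated from a
#'   mutation-level POV via [aggregate_cpov()]); when supplied the
#'   cluster-level test is skipped.
#' @param alpha per-test significance level for the CPOV tests.
#' @param control [ga_control()] search parameters.
#' @param seed optional integer seed for the whole search.
#' @return object of class `subclone_fit` with components `best_tree`,
#'   `max_fitness_set`, `consensus` (edge supports over the tied set),
#'   `sizes` (subclone size fractions under the best tree), `score`, `cpov`,
#'   `cellularity`, `ga` (the full `ga_result`), `alpha`, `seed`, `call`.
#' @examples
#' tr <- subclone_tree(c(A = "GERMLINE", B = "A", C = "B"))
#' set.seed(1)
#' cell <- simulate_cellularities(tr, 4)
#' cm <- cellularity_matrix(cell, matrix(0.02, nrow(cell), ncol(cell)))
#' fit <- fit_subclone_tree(cm, control = ga_control(generation_size = 100,
#'                          generations = 5, runs = 2), seed = 7)
#' fit
#' @export
fit_subclone_tree <- function(cellularity, cpov = NULL, alpha = 0.05,
                              control = ga_control(), seed = NULL) {
  if (!inherits(cellularity, "cellularity_matrix")) {
    stop("'cellularity' must be a cellularity_matrix", call. = FALSE)
  }
  if (is.null(cpov)) cpov <- cluster_cpov(cellularity, alpha)
  ga <- run_ga(cpov, cellularity, control = control, seed = seed)
  best <- ga$max_fitness_set[[1L]]
  sizes <- withCallingHandlers(
    subclone_sizes(best, cellularity),
    warning = function(w) invokeRestart("muffleWarning"))
  fit <- list(best_tree = best,
              max_fitness_set = ga$max_fitness_set,
              consensus = consensus_edges(ga$max_fitness_set),
              sizes = sizes,
              score = ga$max_fitness_score,
              cpov = cpov, cellularity = cellularity, ga = ga,
              alpha = alpha, seed = seed, call = match.call())
  class(fit) <- "subclone_fit"
  fit
}

#' @export
print.subclone_fit <- function(x, ...) {
  cat("Subclone tree fit (", length(x$best_tree$clusters), " clusters, ",
      ncol(x$cellularity$value), " samples)\n", sep = "")
  cat("Maximum fitness:", format(x$ga$max_fitness, digits = 6),
      "(topology cost", format(x$score$topology_cost, digits = 4),
      "+ mass cost", format(x$score$mass_cost, digits = 4), ")\n")
  nt <- length(x$max_fitness_set)
  if (nt > 1L) cat(nt, "trees tied at maximum fitness; best shown\n")
  print(x$best_tree)
  invisible(x)
}

#' @export
summary.subclone_fit <- function(object, ...) {
  out <- list(n_clusters = length(object$best_tree$clusters),
              n_samples = ncol(object$cellularity$value),
              n_topologies_sampled = nrow(object$ga$ensemble),
              n_max_fitness = length(object$max_fitness_set),
              max_fitness = object$ga$max_fitness,
              score = object$score,
              consensus = object$consensus,
              sizes = object$sizes,
              alpha = object$alpha)
  class(out) <- "summary.subclone_fit"
  out
}

#' @export
print.summary.subclone_fit <- function(x, ...) {
  cat("Subclone tree fit:", x$n_clusters, "clusters,", x$n_samples,
      "samples\n")
  cat("Topologies sampled:", x$n_topologies_sampled,
      "| maximum-fitness set size:", x$n_max_fitness,
      "| fitness:", format(x$max_fitness, digits = 6), "\n\n")
  cat("Edge support over the maximum-fitness set:\n")
  print(x$consensus, row.names = FALSE)
  cat("\nSubclone sizes (fraction of cancer cells) under the best tree:\n")
  print(round(x$sizes, 4))
  invisible(x)
}

# simple layered layout: depth on y, leaves spread on x
tree_layout <- function(tree) {
  p <- tree_to_idx(tree)
  n <- length(p)
  depth <- integer(n)
  for (j in seq_len(n)) {
    a <- p[j]
    while (a != 0L) { depth[j] <- depth[j] + 1L; a <- p[a] }
  }
  x <- rep(NA_real_, n)
  leaf_pos <- 0
  assign_x <- function(i) {
    kids <- which(p == i)
    if (!length(kids)) {
      leaf_pos <<- leaf_pos + 1
      x[i] <<- leaf_pos
    } else {
      for (k in kids) assign_x(k)
      x[i] <<- mean(x[kids])
    }
  }
  for (f in which(p == 0L)) assign_x(f)
  list(x = c(mean(x[p == 0L]), x), y = c(0, -(depth + 1L)),
       labels = c(GERMLINE, tree$clusters),
       edges = cbind(ifelse(p == 0L, 1L, p + 1L), seq_len(n) + 1L))
}

#' Plot a fitted subclone tree
#'
#' Draws the maximum-fitness tree with base graphics; when the fit carries
#' ties, edges are annotated with their support across the tied set.
#'
#' @param x a `subclone_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subclone_fit <- function(x, ...) {
  plot(x$best_tree, supports = x$consensus, ...)
}

#' @rdname plot.subclone_fit
#' @param supports optional edge-support data.frame from [consensus_edges()].
#' @export
plot.subclone_tree <- function(x, supports = NULL, ...) {
  ly <- tree_layout(x)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  plot(ly$x, ly$y, type = "n", axes = FALSE, xlab = "", ylab = "",
       xlim = range(ly$x) + c(-0.5, 0.5), ylim = range(ly$y) + c(-0.5, 0.5),
       ...)
  sup <- NULL
  if (!is.null(supports)) {
    key <- paste(supports$parent, supports$child, sep = ">")
    ek <- paste(x$parent[x$clusters], x$clusters, sep = ">")
    sup <- supports$support[match(ek, key)]
  }
  for (e in seq_len(nrow(ly$edges))) {
    i <- ly$edges[e, 1L]; j <- ly$edges[e, 2L]
    graphics::segments(ly$x[i], ly$y[i], ly$x[j], ly$y[j], col = "grey40")
    if (!is.null(sup) && !is.na(sup[e]) && sup[e] < 1) {
      graphics::text((ly$x[i] + ly$x[j]) / 2, (ly$y[i] + ly$y[j]) / 2,
                     sprintf("%.2f", sup[e]), cex = 0.7, col = "firebrick")
    }
  }
  graphics::points(ly$x, ly$y, pch = 21, bg = c("grey80",
                   rep("lightsteelblue", length(ly$x) - 1L)), cex = 3)
  graphics::text(ly$x, ly$y, ly$labels, cex = 0.7)
  invisible(x)
}

#' Simulate datasets from a fitted subclone tree
#'
#' Draws new multi-sample datasets using the fitted maximum-fitness topology
#' as the generating tree.
#'
#' @param object a `subclone_fit`.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param n_samples,purity,coverage,lambda forwarded to
#'   [simulate_dataset()]; `n_samples` defaults to the fitted sample count.
#' @param ... unused.
#' @return list of `sim_dataset` objects.
#' @export
simulate.subclone_fit <- function(object, nsim = 1, seed = NULL,
                                  n_samples = NULL, purity = 0.9,
                                  coverage = 1000, lambda = 10, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_samples)) n_samples <- ncol(object$cellularity$value)
  replicate(nsim,
            simulate_dataset(object$best_tree, n_samples, purity, coverage,
                             lambda),
            simplify = FALSE)
}

#' Residual lineage-divergence violations of a fitted tree
#'
#' Per-node, per-sample mass-cost terms of the best tree: the amount by
#' which each node's children exceed it in cellularity (zero when the
#' divergence rule holds).
#'
#' @param object a `subclone_fit`.
#' @param ... unused.
#' @return numeric matrix (`GERMLINE` plus clusters, by samples).
#' @export
residuals.subclone_fit <- function(object, ...) {
  sc <- score_idx(tree_to_idx(object$best_tree),
                  NULL, align_cell(object$best_tree, object$cellularity),
                  detail = TRUE)
  m <- sc$sample_mass_cost
  dimnames(m) <- list(c(GERMLINE, object$best_tree$clusters),
                      colnames(object$cellularity$value))
  m
}
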