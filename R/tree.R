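#' @title Rooted subclone trees
#'
#' @description A subclone tree is a rooted labeled tree with a germline root
#' (no mutations) and one mutation cluster per edge. Because every non-root
#' node is identified with the cluster on its upstream edge, the whole
#' topology is encoded by a parent map over cluster labels, with exactly one
#' cluster (the founder clone) attached directly below the germline.
#'
#' @param parent named character vector; `names(parent)` are the cluster
#'   labels and `parent[k]` is the label of the parent cluster of `k`, or
#'   `"GERMLINE"` for the founder clone.
#' @return An object of class `subclone_tree` with elements `clusters`
#'   (label vector, in the order given) and `parent` (the validated map).
#' @examples
#' tr <- subclone_tree(c(A = "GERMLINE", B = "A", C = "A"))
#' tree_edges(tr)
#' @export
subclone_tree <- function(parent) {
  if (!is.character(parent) || is.null(names(parent)) ||
      anyNA(parent) || any(names(parent) == "")) {
    stop("'parent' must be a fully named character vector", call. = FALSE)
  }
  tree <- structure(list(clusters = names(parent), parent = parent),
                    class = "subclone_tree")
  validate_tree(tree)
  tree
}

#' Label used for the germline root
#' @export
GERMLINE <- "GERMLINE"

# Internal integer encoding: parent index per cluster position, 0 = germline.
tree_to_idx <- function(tree, clusters = tree$clusters) {
  p <- match(tree$parent[clusters], clusters)
  p[tree$parent[clusters] == GERMLINE] <- 0L
  as.integer(p)
}

idx_to_tree <- function(parent_idx, clusters) {
  parent <- rep(GERMLINE, length(parent_idx))
  nz <- parent_idx != 0L
  parent[nz] <- clusters[parent_idx[nz]]
  names(parent) <- clusters
  structure(list(clusters = clusters, parent = parent),
            class = "subclone_tree")
}

# Fast validity check on the integer encoding: exactly one root child and
# every pointer chain reaches the germline without cycling.
idx_is_valid <- function(parent_idx) {
  n <- length(parent_idx)
  if (n == 0L || sum(parent_idx == 0L) != 1L) return(FALSE)
  if (any(parent_idx < 0L | parent_idx > n)) return(FALSE)
  if (any(parent_idx == seq_len(n))) return(FALSE)
  for (j in seq_len(n)) {
    a <- parent_idx[j]
    steps <- 0L
    while (a != 0L) {
      a <- parent_idx[a]
      steps <- steps + 1L
      if (steps > n) return(FALSE)
    }
  }
  TRUE
}

validate_tree <- function(tree) {
  cl <- tree$clusters
  if (anyDuplicated(cl)) stop("duplicate cluster labels", call. = FALSE)
  if (GERMLINE %in% cl) stop("'GERMLINE' is reserved for the root", call. = FALSE)
  bad <- setdiff(tree$parent, c(cl, GERMLINE))
  if (length(bad)) {
    stop("unknown parent label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!idx_is_valid(tree_to_idx(tree))) {
    stop("invalid topology: need exactly one founder clone and an acyclic, ",
         "fully connected parent map", call. = FALSE)
  }
  invisible(tree)
}

#' Check whether an object is a valid subclone tree
#' @param x object to test.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_tree <- function(x) {
  inherits(x, "subclone_tree") &&
    !is.null(tryCatch(validate_tree(x), error = function(e) NULL))
}

#' Directed edge list of a subclone tree
#' @param tree a `subclone_tree`.
#' @return data.frame with columns `parent` and `child`; the germline edge is
#'   included.
#' @export
tree_edges <- function(tree) {
  data.frame(parent = unname(tree$parent), child = tree$clusters,
             stringsAsFactors = FALSE)
}

edge_keys <- function(tree) {
  paste(tree$parent[tree$clusters], tree$clusters, sep = ">")
}

#' Canonical string form of a topology (used for deduplication)
#' @param tree a `subclone_tree`.
#' @return single string; equal iff the topologies are identical.
#' @export
canonical_form <- function(tree) {
  paste(sort(edge_keys(tree)), collapse = ";")
}

# descendants of cluster index c under integer parent map
idx_descendants <- function(parent_idx, c) {
  desc <- integer(0)
  frontier <- which(parent_idx == c)
  while (length(frontier)) {
    desc <- c(desc, frontier)
    frontier <- which(parent_idx %in% frontier)
  }
  desc
}

# n x n logical matrix; [i, j] TRUE iff i is a proper ancestor of j
idx_ancestor_matrix <- function(parent_idx) {
  n <- length(parent_idx)
  A <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    a <- parent_idx[j]
    while (a != 0L) {
      A[a, j] <- TRUE
      a <- parent_idx[a]
    }
  }
  A
}

#' Ancestor relation of a subclone tree
#' @param tree a `subclone_tree`.
#' @return logical matrix with cluster dimnames; entry (i, j) is `TRUE` iff
#'   cluster i lies on the path from the germline to cluster j (proper
#'   ancestry, so the diagonal is `FALSE`).
#' @export
ancestor_matrix <- function(tree) {
  A <- idx_ancestor_matrix(tree_to_idx(tree))
  dimnames(A) <- list(tree$clusters, tree$clusters)
  A
}

#' Generate a random tree topology
#'
#' Implements the sequential attachment process used to seed the genetic
#' algorithm: the founder clone is drawn uniformly, then each remaining
#' cluster (in uniformly random order) is attached below a uniformly chosen
#' already-placed non-root node.
#'
#' @param clusters character vector of cluster labels.
#' @return a `subclone_tree`.
#' @export
random_topology <- function(clusters) {
  n <- length(clusters)
  if (n < 1L) stop("need at least one cluster", call. = FALSE)
  ord <- sample.int(n)
  parent_idx <- integer(n)
  parent_idx[ord[1L]] <- 0L
  if (n > 1L) {
    for (k in 2:n) {
      parent_idx[ord[k]] <- ord[sample.int(k - 1L, 1L)]
    }
  }
  idx_to_tree(parent_idx, clusters)
}

# Vectorised batch version used by the GA: m trees as an m x n integer matrix.
random_topology_batch <- function(n, m) {
  P <- matrix(0L, m, n)
  if (n == 1L || m == 0L) return(P)
  ords <- matrix(0L, m, n)
  for (i in seq_len(m)) ords[i, ] <- sample.int(n)
  rows <- seq_len(m)
  for (k in 2:n) {
    pick <- 1L + as.integer(floor(stats::runif(m) * (k - 1L)))
    P[cbind(rows, ords[, k])] <- ords[cbind(rows, pick)]
  }
  P
}

#' Enumerate all single-founder topologies
#'
#' Exhaustively lists every rooted labeled tree over the given clusters with
#' one germline child. There are `n^(n-1)` of them for `n` clusters, so the
#' function refuses `n > 7` and points larger problems at [run_ga()].
#'
#' @param clusters character vector of cluster labels (at most 7).
#' @return list of `subclone_tree` objects, no duplicates.
#' @export
enumerate_topologies <- function(clusters) {
  n <- length(clusters)
  if (n < 1L) stop("need at least one cluster", call. = FALSE)
  if (n > 7L) {
    stop("exhaustive enumeration is limited to 7 clusters (n^(n-1) trees); ",
         "use the genetic algorithm (run_ga) instead", call. = FALSE)
  }
  if (n == 1L) return(list(idx_to_tree(0L, clusters)))
  # candidate parent vectors: founder f gets 0, everyone else any other cluster
  out <- vector("list", n^(n - 1L))
  cnt <- 0L
  for (f in seq_len(n)) {
    rest <- setdiff(seq_len(n), f)
    choices <- lapply(rest, function(j) setdiff(seq_len(n), j))
    grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
    P <- matrix(0L, nrow(grid), n)
    P[, rest] <- as.integer(grid)
    # vectorised pointer chase: after n hops every chain must be at the root
    cur <- P
    m <- nrow(P)
    for (k in seq_len(n)) {
      pos <- which(cur > 0L)
      if (!length(pos)) break
      rows <- ((pos - 1L) %% m) + 1L
      cur[pos] <- P[cbind(rows, cur[pos])]
    }
    ok <- which(rowSums(cur != 0L) == 0L)
    for (r in ok) {
      cnt <- cnt + 1L
      out[[cnt]] <- idx_to_tree(P[r, ], clusters)
    }
  }
  out[seq_len(cnt)]
}

#' Jaccard similarity of two tree topologies
#'
#' Edge-set Jaccard index over directed (parent, child) label pairs,
#' including the germline edge.
#'
#' @param a,b `subclone_tree` objects over the same cluster set.
#' @return fraction in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  if (!setequal(a$clusters, b$clusters)) {
    stop("trees must share the same cluster set", call. = FALSE)
  }
  ea <- edge_keys(a)
  eb <- edge_keys(b)
  length(intersect(ea, eb)) / length(union(ea, eb))
}

#' Edge support across a set of trees
#'
#' For every directed edge appearing in any of the trees, the fraction of
#' trees that contain it — the numbers used to label consensus topologies.
#'
#' @param trees nonempty list of `subclone_tree` objects over a common
#'   cluster set.
#' @return data.frame with columns `parent`, `child`, `support` (in (0, 1\]),
#'   sorted by decreasing support.
#' @export
consensus_edges <- function(trees) {
  if (!length(trees)) stop("empty tree list", call. = FALSE)
  cl <- trees[[1L]]$clusters
  for (t in trees) {
    if (!setequal(t$clusters, cl)) {
      stop("trees must share the same cluster set", call. = FALSE)
    }
  }
  keys <- unlist(lapply(trees, edge_keys))
  tab <- table(keys) / length(trees)
  parts <- strsplit(names(tab), ">", fixed = TRUE)
  out <- data.frame(parent = vapply(parts, `[`, "", 1L),
                    child = vapply(parts, `[`, "", 2L),
                    support = as.numeric(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$support, out$parent, out$child), , drop = FALSE]
}

#' @export
print.subclone_tree <- function(x, ...) {
  cat("Subclone tree with", length(x$clusters), "cluster(s)\n")
  e <- tree_edges(x)
  cat(paste0("  ", e$parent, " -> ", e$child), sep = "\n")
  invisible(x)
}
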