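#' Generalized likelihood ratio statistic for lineage precedence
#'
#' Tests, for an ordered pair of mutations (or clusters) i and j, the null
#' hypothesis that i *can be* an ancestor of j. Under the lineage precedence
#' rule an ancestor's cellularity is at least its descendant's in every
#' sample, so the null constrains every per-sample cellularity difference
#' `d_s = C_i_s - C_j_s` to be non-negative. Maximising the normal
#' likelihood over that one-sided parameter space yields
#' \deqn{T = -2\log\Lambda = \sum_s (\hat d_s/\sigma_s)^2 \, I(\hat d_s < 0)}
#' i.e. only samples where the ordering is observed violated contribute,
#' each as a squared z-score. Ties (`d_s == 0`) contribute nothing.
#'
#' @param dhat numeric vector of observed per-sample cellularity differences.
#' @param sigma positive per-sample standard deviations of `dhat` (in
#'   practice pooled standard errors, `sqrt(se_i^2 + se_j^2)`).
#' @return the statistic `T >= 0`.
#' @export
glrt_statistic <- function(dhat, sigma) {
  if (length(dhat) != length(sigma) || !length(dhat)) {
    stop("'dhat' and 'sigma' must be equal-length, nonempty", call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("all 'sigma' must be positive and finite", call. = FALSE)
  }
  sum((dhat / sigma)^2 * (dhat < 0))
}

#' Mixture weights of the conservative null distribution
#'
#' Under the reduced null (all true differences exactly zero) the statistic
#' is distributed as a mixture of chi-square variables with `k = 0, ..., S`
#' degrees of freedom and binomial weights `choose(S, k) / 2^S` — each k
#' corresponds to observing exactly k negative z-scores among S independent
#' standard normals. Weights are computed in exact integer arithmetic and
#' normalised.
#'
#' @param S number of samples.
#' @return numeric vector of length `S + 1` summing to 1, for df `0:S`.
#' @export
null_mixture_weights <- function(S) {
  if (length(S) != 1L || S < 1L || S != round(S)) {
    stop("'S' must be a positive integer", call. = FALSE)
  }
  w <- choose(S, 0:S)
  w / sum(w)
}

#' Tail probability of the chi-square mixture null
#'
#' `P(T_null >= T)` where `T_null` follows the conservative mixture null for
#' `S` samples; the df-0 component is a point mass at zero and contributes
#' its full weight iff `T <= 0`.
#'
#' @param T observed statistic(s); vector or matrix (elementwise).
#' @param S number of samples.
#' @return p-value(s), same shape as `T`.
#' @export
null_tail_probability <- function(T, S) {
  w <- null_mixture_weights(S)
  p <- w[1L] * (T <= 0)
  for (k in seq_len(S)) {
    p <- p + w[k + 1L] * stats::pchisq(T, df = k, lower.tail = FALSE)
  }
  p
}

#' Pairwise lineage-precedence hypothesis test
#'
#' @param ci,cj per-sample cellularity estimates for the candidate ancestor
#'   (`ci`) and descendant (`cj`): each a list or data.frame with numeric
#'   elements `value` and `stderr`, aligned by sample (same names if named).
#' @param alpha per-test significance level (the framework uses a fixed
#'   common level, default 0.05, with no multiplicity correction).
#' @return object of class `precedence_test` with elements `dhat`, `sigma`,
#'   `zscores`, `statistic`, `likelihood_ratio`, `pvalue`, `alpha`, `reject`.
#' @examples
#' a <- list(value = c(0.9, 0.8), stderr = c(0.05, 0.05))
#' b <- list(value = c(0.4, 0.5), stderr = c(0.05, 0.05))
#' test_precedence(a, b)
#' @export
test_precedence <- function(ci, cj, alpha = 0.05) {
  if (length(ci$value) != length(cj$value)) {
    stop("'ci' and 'cj' must cover the same samples", call. = FALSE)
  }
  if (!is.null(names(ci$value)) && !is.null(names(cj$value)) &&
      !identical(names(ci$value), names(cj$value))) {
    stop("sample names of 'ci' and 'cj' disagree", call. = FALSE)
  }
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  dhat <- ci$value - cj$value
  sigma <- sqrt(ci$stderr^2 + cj$stderr^2)
  if (anyNA(sigma)) stop("missing standard errors", call. = FALSE)
  T <- glrt_statistic(dhat, sigma)
  p <- null_tail_probability(T, length(dhat))
  structure(list(dhat = dhat, sigma = sigma, zscores = dhat / sigma,
                 statistic = T, likelihood_ratio = exp(-T / 2),
                 pvalue = p, alpha = alpha, reject = p < alpha),
            class = "precedence_test")
}

#' @export
print.precedence_test <- function(x, ...) {
  cat("Lineage precedence test (", length(x$dhat), " samples)\n", sep = "")
  cat("  T =", format(x$statistic, digits = 6),
      " p =", format(x$pvalue, digits = 4),
      " ->", if (x$reject) "reject (cannot be ancestor)" else
        "not rejected (can be ancestor)", "\n")
  invisible(x)
}

# Vectorised all-pairs statistic matrix from a cellularity matrix.
pairwise_statistic <- function(V, E) {
  n <- nrow(V)
  T <- matrix(0, n, n, dimnames = list(rownames(V), rownames(V)))
  for (s in seq_len(ncol(V))) {
    D <- outer(V[, s], V[, s], `-`)
    S2 <- outer(E[, s]^2, E[, s]^2, `+`)
    T <- T + (D * D / S2) * (D < 0)
  }
  T
}

#' Precedence order violation matrix
#'
#' Runs the precedence test for every ordered pair of entities in a
#' cellularity matrix. Entry (i, j) is 1 iff the hypothesis that i can be an
#' ancestor of j is rejected at level `alpha`. The diagonal is zero by
#' construction (an entity trivially "precedes" itself).
#'
#' @param cm a [cellularity_matrix()] with complete standard errors.
#' @param alpha per-test significance level.
#' @return binary integer matrix with entity dimnames.
#' @export
build_pov <- function(cm, alpha = 0.05) {
  if (nrow(cm$value) < 2L) stop("need at least two entities", call. = FALSE)
  if (anyNA(cm$stderr)) stop("standard errors required for testing", call. = FALSE)
  T <- pairwise_statistic(cm$value, cm$stderr)
  P <- null_tail_probability(T, ncol(cm$value))
  pov <- (P < alpha) + 0L
  storage.mode(pov) <- "integer"
  diag(pov) <- 0L
  pov
}

#' Vote-aggregate a mutation POV matrix into a cluster CPOV matrix
#'
#' Entry (I, J) is the mean of the POV block formed by the member mutations
#' of clusters I and J — the fraction of member-pair tests rejecting
#' precedence. Diagonal blocks are computed by the same formula (POV's own
#' diagonal is zero, so the within-cluster entry is the fraction of rejected
#' ordered member pairs over `|M(I)|^2`); downstream tree scoring never
#' consults the diagonal.
#'
#' @param pov binary POV matrix from [build_pov()].
#' @param assignment named character vector mapping mutation id to cluster id;
#'   every POV row must be assigned.
#' @return numeric matrix with entries in \[0, 1\] and cluster dimnames.
#' @export
aggregate_cpov <- function(pov, assignment) {
  muts <- rownames(pov)
  missing <- setdiff(muts, names(assignment))
  if (length(missing)) {
    stop("unassigned mutation(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cl <- factor(assignment[muts])
  ids <- levels(cl)
  sizes <- as.numeric(table(cl))
  # block sums via indicator matrices
  Z <- stats::model.matrix(~ cl - 1)
  sums <- t(Z) %*% pov %*% Z
  cpov <- sums / outer(sizes, sizes)
  dimnames(cpov) <- list(ids, ids)
  cpov
}

#' Cluster-level CPOV matrix from direct cluster tests
#'
#' Applies the precedence test to pairs of clusters (rather than pairs of
#' member mutations), producing a binary CPOV matrix.
#'
#' @param cm cluster-level [cellularity_matrix()] with standard errors.
#' @param alpha per-test significance level.
#' @return binary integer matrix with cluster dimnames.
#' @export
cluster_cpov <- function(cm, alpha = 0.05) {
  build_pov(cm, alpha)
}
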