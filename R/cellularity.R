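#' Naive cellularity estimate from read counts
#'
#' Converts variant/reference read counts at a locus into an estimate of the
#' fraction of cancer cells carrying the mutation, assuming the locus sits in
#' a diploid (total copy number 2) or hemizygous (copy number 1) region of
#' the tumor genome and that normal contamination is diploid. The point
#' estimate is
#' \deqn{C = \hat f \cdot \frac{CN \cdot p + 2(1-p)}{m \cdot p}}
#' where \eqn{\hat f} is the variant allele fraction, \eqn{p} the sample
#' purity, \eqn{CN} the tumor copy number and \eqn{m} the number of copies
#' bearing the mutation. The standard error is obtained by the delta method
#' from the binomial sampling variance of the VAF, using the smoothed
#' fraction \eqn{\tilde f = (v + 0.5)/(N + 1)} so that loci observed at VAF
#' 0 or 1 keep a positive standard error; the result is floored at `1e-4`
#' because downstream test statistics divide by it.
#'
#' @param var_count,ref_count non-negative integer read counts (vectorised).
#' @param purity sample purity in (0, 1].
#' @param copy_number tumor total copy number at the locus; only 1 and 2 are
#'   supported by the naive estimator.
#' @param multiplicity number of copies bearing the mutation (default 1).
#' @return data.frame with columns `value` (clamped to \[0, 1\]), `stderr`,
#'   `unclamped` and `clamped` (logical).
#' @examples
#' naive_cellularity(30, 70, purity = 0.8)
#' @export
naive_cellularity <- function(var_count, ref_count, purity,
                              copy_number = 2L, multiplicity = 1L) {
  k <- max(length(var_count), length(ref_count), length(copy_number),
           length(multiplicity))
  var_count <- rep_len(var_count, k)
  ref_count <- rep_len(ref_count, k)
  copy_number <- rep_len(copy_number, k)
  multiplicity <- rep_len(multiplicity, k)
  if (length(purity) != 1L || is.na(purity) || purity <= 0 || purity > 1) {
    stop("'purity' must be a single value in (0, 1]", call. = FALSE)
  }
  if (any(var_count < 0) || any(ref_count < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (!all(copy_number %in% c(1L, 2L))) {
    stop("naive estimator supports copy_number 1 (hemizygous) or 2 (diploid) ",
         "only; got ", paste(unique(setdiff(copy_number, 1:2)), collapse = ", "),
         call. = FALSE)
  }
  if (any(multiplicity < 1)) stop("'multiplicity' must be >= 1", call. = FALSE)
  n <- var_count + ref_count
  if (any(n < 1)) stop("zero sequencing depth: var_count + ref_count must be >= 1",
                       call. = FALSE)
  vaf <- var_count / n
  scale <- (copy_number * purity + 2 * (1 - purity)) / (multiplicity * purity)
  raw <- vaf * scale
  f_sm <- (var_count + 0.5) / (n + 1)
  se <- pmax(scale * sqrt(f_sm * (1 - f_sm) / n), 1e-4)
  data.frame(value = pmin(pmax(raw, 0), 1), stderr = se,
             unclamped = raw, clamped = raw > 1 | raw < 0)
}

#' Cluster cellularity from a mean variant allele fraction
#'
#' Diploid heterozygous conversion of a published cluster mean VAF into a
#' mean cellularity: `2 * mean_vaf / purity`, clamped to \[0, 1\] with a
#' warning when the VAF exceeds half the purity. No standard error is
#' produced; when the result feeds the precedence test the caller must
#' supply one (e.g. from published dispersions or the spread of member
#' mutations).
#'
#' @param mean_vaf mean variant allele fraction in \[0, 1\] (vectorised).
#' @param purity sample purity in (0, 1].
#' @return data.frame with columns `value` and `stderr` (always `NA`).
#' @export
cluster_cellularity_from_vaf <- function(mean_vaf, purity) {
  if (length(purity) != 1L || is.na(purity) || purity <= 0 || purity > 1) {
    stop("'purity' must be a single value in (0, 1]", call. = FALSE)
  }
  if (any(mean_vaf < 0 | mean_vaf > 1)) {
    stop("'mean_vaf' must lie in [0, 1]", call. = FALSE)
  }
  raw <- 2 * mean_vaf / purity
  if (any(raw > 1)) {
    warning("mean VAF exceeds purity/2 for ", sum(raw > 1),
            " value(s); cellularity clamped to 1", call. = FALSE)
  }
  data.frame(value = pmin(raw, 1), stderr = NA_real_)
}

#' Estimate sample purity from clustered mutations
#'
#' Identifies the mutation cluster with the maximum mean variant allele
#' fraction in the sample and, under the diploid heterozygous founder
#' assumption, returns twice that mean VAF, capped at 1.
#'
#' @param records mutation-table data.frame (see [read_mutation_table()])
#'   with a `cluster_id` column.
#' @param sample_id sample to estimate; defaults to the only sample present.
#' @param min_depth minimum read depth for a mutation to be used.
#' @return purity estimate in (0, 1].
#' @export
estimate_purity <- function(records, sample_id = NULL, min_depth = 1L) {
  if (is.null(records$cluster_id)) {
    stop("'records' must carry a cluster_id column", call. = FALSE)
  }
  if (!is.null(sample_id)) records <- records[records$sample_id == sample_id, ]
  depth <- records$var_count + records$ref_count
  records <- records[depth >= min_depth & depth >= 1L, ]
  if (!nrow(records)) {
    stop("no usable mutations to estimate purity from", call. = FALSE)
  }
  vaf <- records$var_count / (records$var_count + records$ref_count)
  cluster_means <- tapply(vaf, records$cluster_id, mean)
  min(1, 2 * max(cluster_means))
}

#' Filter mutations to usable depth and copy-number state
#'
#' @param records mutation-table data.frame.
#' @param min_depth minimum total read depth (inclusive).
#' @param allowed_cn copy-number states to keep; the default keeps diploid
#'   and hemizygous loci, the regions the naive estimator supports.
#' @return the retained rows, original order preserved. The number of
#'   dropped rows is reported with a message; an empty result triggers a
#'   warning.
#' @export
filter_mutations <- function(records, min_depth = 50L, allowed_cn = c(1L, 2L)) {
  if (!nrow(records)) return(records)
  cn <- if (is.null(records$copy_number)) rep(2L, nrow(records)) else records$copy_number
  keep <- (records$var_count + records$ref_count) >= min_depth & cn %in% allowed_cn
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message("filter_mutations: dropped ", dropped, " of ", nrow(records), " records")
  }
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) warning("all mutations filtered out", call. = FALSE)
  out
}

#' Cellularity matrix container
#'
#' Holds cellularity point estimates and their standard errors on a complete
#' entity-by-sample grid, where entities are mutations or mutation clusters.
#'
#' @param value numeric matrix (entities x samples) with dimnames.
#' @param stderr matrix of matching shape; standard errors, all positive
#'   (may be `NA` only if the matrix is used for mass cost alone).
#' @return object of class `cellularity_matrix`.
#' @export
cellularity_matrix <- function(value, stderr) {
  value <- as.matrix(value)
  stderr <- as.matrix(stderr)
  if (!all(dim(value) == dim(stderr))) {
    stop("'value' and 'stderr' must have identical shape", call. = FALSE)
  }
  if (is.null(rownames(value)) || is.null(colnames(value))) {
    stop("'value' needs entity rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(value)) stop("cellularity grid must be complete", call. = FALSE)
  if (any(stderr <= 0, na.rm = TRUE)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  dimnames(stderr) <- dimnames(value)
  structure(list(value = value, stderr = stderr), class = "cellularity_matrix")
}

#' @export
print.cellularity_matrix <- function(x, ...) {
  cat("Cellularity matrix:", nrow(x$value), "entit(ies) x",
      ncol(x$value), "sample(s)\n")
  print(round(x$value, 4))
  invisible(x)
}

#' Build a mutation-level cellularity matrix from a mutation table
#'
#' Applies the naive estimator to every (mutation, sample) record and
#' assembles the complete grid.
#'
#' @param records mutation-table data.frame covering every mutation in every
#'   sample exactly once.
#' @param purity either a single purity shared by all samples or a named
#'   vector with one entry per sample.
#' @return a [cellularity_matrix()].
#' @export
mutation_cellularity_matrix <- function(records, purity) {
  muts <- unique(records$mutation_id)
  samples <- unique(records$sample_id)
  if (length(purity) == 1L && is.null(names(purity))) {
    purity <- stats::setNames(rep(purity, length(samples)), samples)
  }
  missing_p <- setdiff(samples, names(purity))
  if (length(missing_p)) {
    stop("no purity given for sample(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  V <- matrix(NA_real_, length(muts), length(samples),
              dimnames = list(muts, samples))
  E <- V
  for (s in samples) {
    rs <- records[records$sample_id == s, ]
    if (anyDuplicated(rs$mutation_id)) {
      stop("duplicate records for sample ", s, call. = FALSE)
    }
    est <- naive_cellularity(rs$var_count, rs$ref_count, purity[[s]],
                             if (is.null(rs$copy_number)) 2L else rs$copy_number,
                             if (is.null(rs$multiplicity)) 1L else rs$multiplicity)
    V[rs$mutation_id, s] <- est$value
    E[rs$mutation_id, s] <- est$stderr
  }
  if (anyNA(V)) {
    stop("incomplete grid: every mutation must be observed in every sample",
         call. = FALSE)
  }
  cellularity_matrix(V, E)
}

#' Collapse a mutation-level cellularity matrix to cluster means
#'
#' Cluster values are the means of their member mutations' estimates; the
#' standard error of each mean combines the members' standard errors under
#' independence, `sqrt(sum(se_i^2)) / k`, floored at `1e-4`.
#'
#' @param cm a mutation-level [cellularity_matrix()].
#' @param assignment named character vector mapping mutation id to cluster id.
#' @return a cluster-level [cellularity_matrix()].
#' @export
cluster_mean_cellularity <- function(cm, assignment) {
  muts <- rownames(cm$value)
  missing <- setdiff(muts, names(assignment))
  if (length(missing)) {
    stop("unassigned mutation(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cl <- assignment[muts]
  ids <- sort(unique(cl))
  V <- matrix(NA_real_, length(ids), ncol(cm$value),
              dimnames = list(ids, colnames(cm$value)))
  E <- V
  for (id in ids) {
    members <- which(cl == id)
    k <- length(members)
    V[id, ] <- colMeans(cm$value[members, , drop = FALSE])
    E[id, ] <- pmax(sqrt(colSums(cm$stderr[members, , drop = FALSE]^2)) / k, 1e-4)
  }
  cellularity_matrix(V, E)
}
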