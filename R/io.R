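input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cloneTree_input_error", "error")))
}

#' Read a mutation table
#'
#' Tab-separated, header required, columns `mutation_id`, `sample_id`,
#' `ref_count`, `var_count`, and optionally `copy_number`, `multiplicity`,
#' `cluster_id`. Unknown extra columns are kept with a warning. Duplicate
#' (mutation, sample) pairs and non-integer counts are rejected with the
#' offending rows named.
#'
#' @param path path to the TSV file.
#' @return data.frame of typed records, one row per (mutation, sample).
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) input_error("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("mutation_id", "sample_id", "ref_count", "var_count")
  optional <- c("copy_number", "multiplicity", "cluster_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    input_error("missing required column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  for (col in intersect(c("ref_count", "var_count", "copy_number",
                          "multiplicity"), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      bad <- which(!grepl("^[0-9]+$", as.character(v)))
      input_error("column '", col, "' must hold non-negative integers (rows ",
                  paste(utils::head(bad, 5L), collapse = ", "), ")")
    }
    df[[col]] <- as.integer(v)
  }
  key <- paste(df$mutation_id, df$sample_id)
  if (anyDuplicated(key)) {
    dup <- which(key %in% key[duplicated(key)])
    input_error("duplicate (mutation, sample) pairs at rows ",
                paste(dup, collapse = ", "))
  }
  df
}

#' Read / write a cellularity table
#'
#' Long-format TSV with columns `entity_id`, `sample_id`, `cellularity`,
#' `sd`; the reader assembles a complete [cellularity_matrix()].
#'
#' @param path file path.
#' @return `read_cellularity_table`: a [cellularity_matrix()].
#' @export
read_cellularity_table <- function(path) {
  if (!file.exists(path)) input_error("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("entity_id", "sample_id", "cellularity", "sd")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    input_error("missing required column(s): ", paste(missing, collapse = ", "))
  }
  entities <- unique(df$entity_id)
  samples <- unique(df$sample_id)
  V <- matrix(NA_real_, length(entities), length(samples),
              dimnames = list(entities, samples))
  E <- V
  V[cbind(df$entity_id, df$sample_id)] <- df$cellularity
  E[cbind(df$entity_id, df$sample_id)] <- df$sd
  if (anyNA(V)) input_error("incomplete (entity, sample) grid in ", path)
  cellularity_matrix(V, E)
}

#' @rdname read_cellularity_table
#' @param cm a [cellularity_matrix()].
#' @param comment optional `# comment` header lines (e.g. the seed used).
#' @export
write_cellularity_table <- function(cm, path, comment = NULL) {
  df <- data.frame(
    entity_id = rep(rownames(cm$value), ncol(cm$value)),
    sample_id = rep(colnames(cm$value), each = nrow(cm$value)),
    cellularity = sprintf("%.6f", as.vector(cm$value)),
    sd = sprintf("%.6f", as.vector(cm$stderr)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a POV / CPOV matrix
#'
#' Square TSV with row and column headers (binary 0/1 for POV, 6-decimal
#' fractions for CPOV), plus optionally a long-format companion
#' (`from  to  value`) convenient for heat maps.
#'
#' @param m square matrix with dimnames.
#' @param path output path for the square TSV.
#' @param long_path optional output path for the long format.
#' @export
write_pov <- function(m, path, long_path = NULL) {
  fmt <- if (all(m == round(m))) format(m) else
    matrix(sprintf("%.6f", m), nrow(m), dimnames = dimnames(m))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  if (!is.null(long_path)) {
    long <- data.frame(from = rep(rownames(m), ncol(m)),
                       to = rep(colnames(m), each = nrow(m)),
                       value = sprintf("%.6f", as.vector(m)))
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a square POV / CPOV TSV back into a matrix
#' @param path file written by [write_pov()].
#' @return numeric matrix with dimnames.
#' @export
read_pov <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' Serialize a tree to JSON and an edge list
#'
#' @param tree a `subclone_tree`.
#' @param score optional `tree_score` to embed.
#' @param supports optional edge-support data.frame from [consensus_edges()].
#' @return list with `json` (single JSON string with stable keys `clusters`,
#'   `parent_map` and optionally `fitness`, `topology_cost`, `mass_cost`)
#'   and `edges` (data.frame `parent`, `child`, `support`).
#' @export
serialize_tree <- function(tree, score = NULL, supports = NULL) {
  obj <- list(clusters = tree$clusters,
              parent_map = as.list(tree$parent))
  if (!is.null(score)) {
    obj$fitness <- score$fitness
    obj$topology_cost <- score$topology_cost
    obj$mass_cost <- score$mass_cost
  }
  edges <- tree_edges(tree)
  edges$support <- 1
  if (!is.null(supports)) {
    key <- paste(supports$parent, supports$child, sep = ">")
    hit <- match(paste(edges$parent, edges$child, sep = ">"), key)
    edges$support[!is.na(hit)] <- supports$support[hit[!is.na(hit)]]
  }
  list(json = jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA),
       edges = edges)
}

#' Parse a tree serialized by [serialize_tree()]
#' @param json JSON string or path to a JSON file.
#' @return a `subclone_tree`.
#' @export
parse_tree <- function(json) {
  obj <- jsonlite::fromJSON(json)
  subclone_tree(unlist(obj$parent_map)[obj$clusters])
}

#' Newick string of a subclone tree
#'
#' Clusters appear as node labels; the germline root closes the string.
#'
#' @param tree a `subclone_tree`.
#' @return single Newick string, semicolon-terminated.
#' @export
tree_to_newick <- function(tree) {
  p <- tree_to_idx(tree)
  rec <- function(i) {
    kids <- which(p == i)
    lab <- if (i == 0L) GERMLINE else tree$clusters[i]
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")", lab)
  }
  paste0(rec(0L), ";")
}

#' DOT (graphviz) export of a subclone tree
#'
#' @param tree a `subclone_tree`.
#' @param supports optional edge-support data.frame; supports become edge
#'   labels.
#' @return character vector of DOT lines.
#' @export
tree_to_dot <- function(tree, supports = NULL) {
  e <- serialize_tree(tree, supports = supports)$edges
  lab <- if (is.null(supports)) "" else
    sprintf(" [label=\"%.2f\"]", e$support)
  c("digraph subclone_tree {",
    "  node [shape=circle];",
    sprintf("  \"%s\" -> \"%s\"%s;", e$parent, e$child, lab),
    "}")
}

#' Read a run configuration file
#'
#' YAML with optional top-level keys `alpha`, `seed` and any [ga_control()]
#' field; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return list with `alpha`, `seed` and `control` (a `ga_control`).
#' @export
read_run_config <- function(path) {
  cfg_error <- function(...) {
    stop(errorCondition(paste0(...), class = c("cloneTree_config_error", "error")))
  }
  if (!file.exists(path)) cfg_error("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  ga_keys <- setdiff(names(formals(ga_control)), "")
  unknown <- setdiff(names(cfg), c("alpha", "seed", ga_keys))
  if (length(unknown)) {
    cfg_error("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  if (alpha <= 0 || alpha >= 1) cfg_error("alpha must lie in (0, 1)")
  ctrl <- tryCatch(do.call(ga_control, cfg[intersect(names(cfg), ga_keys)]),
                   error = function(e) cfg_error(conditionMessage(e)))
  list(alpha = alpha, seed = cfg$seed, control = ctrl)
}
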