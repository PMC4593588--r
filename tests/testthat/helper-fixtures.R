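# Shared fixtures built in code.

chain_tree <- function(n, labels = paste0("C", seq_len(n))) {
  parent <- c(GERMLINE, labels[-n])
  names(parent) <- labels
  subclone_tree(parent)
}

# 5-node fully branched tree: founder with four children (S1-Fig-A shape)
branched5 <- function() {
  subclone_tree(c(A = "GERMLINE", B = "A", C = "A", D = "A", E = "A"))
}

# CPOV with power 1 / Type-1 error 0 under a given generating tree:
# entry (I, J) is 1 exactly when I is neither J nor an ancestor of J.
perfect_cpov <- function(tree) truth_pov(tree)

# noiseless cluster-level cellularity matrix with small fixed stderr
noiseless_cm <- function(tree, n_samples, stderr = 1e-4) {
  V <- simulate_cellularities(tree, n_samples)
  cellularity_matrix(V, matrix(stderr, nrow(V), ncol(V), dimnames = dimnames(V)))
}

fast_ctrl <- function(...) {
  ga_control(generation_size = 200L, generations = 8L, runs = 2L, ...)
}

expect_same_topology <- function(a, b) {
  expect_identical(canonical_form(a), canonical_form(b))
}
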