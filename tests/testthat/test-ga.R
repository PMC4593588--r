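test_that("roulette selection is fitness-proportional", {
  a <- chain_tree(2, c("A", "B"))
  b <- subclone_tree(c(B = GERMLINE, A = "B"))
  # a pool of one tree always returns that tree
  one <- select_parents(list(a), 1, 50)
  expect_true(all(vapply(one, canonical_form, "") == canonical_form(a)))
  # fitness 1 vs exp(-5): exact roulette probability
  set.seed(60)
  sel <- select_parents(list(a, b), c(1, exp(-5)), 10000)
  frac_a <- mean(vapply(sel, canonical_form, "") == canonical_form(a))
  p <- 1 / (1 + exp(-5))
  expect_lt(abs(frac_a - p), 3 * sqrt(p * (1 - p) / 10000))
  # uniform fitness: uniform selection
  trees <- enumerate_topologies(c("A", "B", "C"))
  set.seed(61)
  sel <- select_parents(trees, rep(1, 9), 9000)
  counts <- table(vapply(sel, canonical_form, ""))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.001)
  expect_error(select_parents(list(), 1, 5), "empty")
  expect_error(select_parents(list(a), 0, 5), "positive")
})

test_that("crossover transplants a cluster onto its parent in the other tree", {
  labels <- c("1", "2", "3")
  a <- chain_tree(3, labels)                       # GL->1->2->3
  b <- subclone_tree(c(`1` = GERMLINE, `3` = "1", `2` = "3"))  # GL->1->3->2
  # a = b: children equal parents
  kids <- crossover_trees(a, a)
  expect_same_topology(kids[[1]], a)
  expect_same_topology(kids[[2]], a)
  # hand-traced: when cluster 3 is picked, child1 moves parent(3) from 2 to
  # 1, giving the branched tree {1->2, 1->3}
  branched <- subclone_tree(c(`1` = GERMLINE, `2` = "1", `3` = "1"))
  set.seed(62)
  seen <- character()
  for (i in 1:50) seen <- c(seen, canonical_form(crossover_trees(a, b)[[1]]))
  expect_true(canonical_form(branched) %in% seen)
  expect_error(crossover_trees(a, chain_tree(3)), "cluster set")
})

test_that("crossover always yields valid trees", {
  set.seed(63)
  labels <- paste0("C", 1:6)
  for (i in 1:1000) {
    pair <- crossover_trees(random_topology(labels), random_topology(labels))
    expect_true(idx_is_valid(tree_to_idx(pair[[1]])))
    expect_true(idx_is_valid(tree_to_idx(pair[[2]])))
  }
})

test_that("mutation applies prune-regraft or label swap and stays valid", {
  # single cluster: identity
  t1 <- random_topology("A")
  expect_same_topology(mutate_tree(t1), t1)
  # n = 2 chain: regraft has no alternative parent (no-op); swap reverses
  ch <- chain_tree(2, c("1", "2"))
  set.seed(64)
  outs <- replicate(200, {
    out <- mutate_tree(ch)
    paste(attr(out, "op"), canonical_form(out))
  })
  rev_ch <- subclone_tree(c(`2` = GERMLINE, `1` = "2"))
  expect_true(all(outs %in% c(paste("regraft", canonical_form(ch)),
                              paste("swap", canonical_form(rev_ch)))))
  # operator frequencies follow p_s
  ops <- sub(" .*", "", outs)
  expect_lt(abs(mean(ops == "regraft") - 0.6), 3 * sqrt(0.6 * 0.4 / 200))
  # fuzz: validity over many applications on larger trees
  labels <- paste0("C", 1:6)
  set.seed(65)
  tr <- random_topology(labels)
  for (i in 1:1000) {
    tr <- mutate_tree(tr)
    expect_true(idx_is_valid(tree_to_idx(tr)))
  }
})

test_that("GA recovers the unique zero-cost tree on noiseless input", {
  # high cellularities so that any sibling placement violates divergence
  tr <- chain_tree(3)
  V <- cbind(S1 = c(1.0, 0.9, 0.8), S2 = c(1.0, 0.8, 0.6))
  rownames(V) <- tr$clusters
  cm <- cellularity_matrix(V, matrix(1e-3, 3, 2, dimnames = dimnames(V)))
  res <- run_ga(cluster_cpov(cm), cm, control = fast_ctrl(), seed = 1)
  expect_identical(length(res$max_fitness_set), 1L)
  expect_same_topology(res$max_fitness_set[[1]], tr)
  expect_equal(res$max_fitness, 1)
})

test_that("GA with topology cost alone reproduces the tie structure", {
  # fully branched: unique maximum-fitness tree equals the generating one
  star <- subclone_tree(c(A = "GERMLINE", B = "A", C = "A", D = "A"))
  res <- run_ga(perfect_cpov(star), NULL, control = fast_ctrl(), seed = 2)
  expect_identical(length(res$max_fitness_set), 1L)
  expect_same_topology(res$max_fitness_set[[1]], star)
  # linear chain: six tied chain-compatible topologies
  ch <- chain_tree(4)
  res <- run_ga(perfect_cpov(ch), NULL, control = fast_ctrl(), seed = 3)
  expect_identical(length(res$max_fitness_set), 6L)
  expect_true(canonical_form(ch) %in%
                vapply(res$max_fitness_set, canonical_form, ""))
})

test_that("maximum-fitness set honors the relative tolerance", {
  tr <- chain_tree(3)
  set.seed(67)
  cm <- noiseless_cm(tr, 4)
  res <- run_ga(cluster_cpov(cm), cm, control = fast_ctrl(), seed = 4)
  expect_identical(length(maximum_fitness_set(res)), 1L)
  # with a huge tolerance every sampled topology joins the set
  expect_identical(length(maximum_fitness_set(res, rel_tol = 1)),
                   nrow(res$ensemble))
})

test_that("GA max-fitness set matches exhaustive enumeration on small instances", {
  set.seed(68)
  for (rep in 1:6) {
    n <- sample(3:5, 1)
    labels <- paste0("C", 1:n)
    tr <- random_topology(labels)
    ds <- simulate_dataset(tr, n_samples = n, purity = 0.7, coverage = 300)
    cm <- mutation_cellularity_matrix(ds$reads, 0.7)
    cpov <- aggregate_cpov(build_pov(cm), ds$assignment)
    ccell <- cluster_mean_cellularity(cm, ds$assignment)$value
    res <- run_ga(cpov, ccell, control = fast_ctrl(), seed = 100 + rep)
    z_all <- vapply(enumerate_topologies(labels), function(t)
      tree_fitness(t, cpov, ccell)$total_cost, 0)
    expect_equal(res$ensemble$total_cost[1], min(z_all), tolerance = 1e-9)
  }
})

test_that("best-so-far fitness trace is non-decreasing within each run", {
  tr <- chain_tree(4)
  set.seed(69)
  cm <- noiseless_cm(tr, 3, stderr = 0.05)
  res <- run_ga(cluster_cpov(cm), cm, control = fast_ctrl(), seed = 5)
  expect_true(all(apply(res$traces, 1, function(x) all(diff(x) >= 0))))
  expect_identical(dim(res$traces), c(2L, 9L))
})

test_that("default cost scaling recovers the truth at least as often as extremes", {
  set.seed(70)
  labels <- paste0("C", 1:5)
  wins <- c(`0.5` = 0, `5` = 0, `50` = 0)
  for (rep in 1:3) {
    tr <- random_topology(labels)
    ds <- simulate_dataset(tr, 5, purity = 0.9, coverage = 1000)
    cm <- mutation_cellularity_matrix(ds$reads, 0.9)
    cpov <- aggregate_cpov(build_pov(cm), ds$assignment)
    ccell <- cluster_mean_cellularity(cm, ds$assignment)$value
    for (fc in c(0.5, 5, 50)) {
      res <- run_ga(cpov, ccell, control = fast_ctrl(fitness_scaling = fc),
                    seed = 200 + rep)
      hit <- canonical_form(tr) %in%
        vapply(res$max_fitness_set, canonical_form, "")
      wins[as.character(fc)] <- wins[as.character(fc)] + hit
    }
  }
  expect_gte(wins[["5"]], max(wins[["0.5"]], wins[["50"]]) - 0L)
})

test_that("GA configuration is validated", {
  expect_error(ga_control(selection_fraction = 0.7), "must equal 1")
  expect_error(ga_control(crossover_prob = 1.2), "probabilities")
  expect_error(ga_control(generation_size = 1), "invalid")
  expect_error(run_ga(NULL, NULL), "at least one")
  expect_error(run_ga(matrix(0, 2, 2)), "dimnames")
})
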