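test_that("topology cost sums CPOV over transitive ancestor pairs", {
  ch <- chain_tree(2, c("1", "2"))
  cpov <- matrix(0, 2, 2, dimnames = list(c("1", "2"), c("1", "2")))
  expect_equal(topology_cost(ch, cpov), 0)
  cpov["1", "2"] <- 1
  rev_ch <- subclone_tree(c(`2` = GERMLINE, `1` = "2"))
  cpov2 <- matrix(0, 2, 2, dimnames = dimnames(cpov))
  cpov2["2", "1"] <- 1
  expect_equal(topology_cost(rev_ch, cpov2), 1)
  # 3-chain with all entries 0.5: ancestor pairs (1,2), (1,3), (2,3)
  ch3 <- chain_tree(3, c("1", "2", "3"))
  cpov3 <- matrix(0.5, 3, 3, dimnames = list(c("1", "2", "3"), c("1", "2", "3")))
  expect_equal(topology_cost(ch3, cpov3), 1.5)
  expect_error(topology_cost(ch3, cpov), "clusters")
})

test_that("mass cost is the summed Euclidean norm of per-sample violations", {
  tr <- subclone_tree(c(P = "GERMLINE", Q = "P", R = "P"))
  V <- rbind(P = c(0.8, 0.7), Q = c(0.5, 0.3), R = c(0.4, 0.2))
  colnames(V) <- c("s1", "s2")
  # children sum 0.9 vs 0.8 in s1 (excess 0.1), 0.5 vs 0.7 in s2 (none)
  expect_equal(as.numeric(mass_cost(tr, V)), sqrt(0.1^2 + 0^2))
  detail <- attr(mass_cost(tr, V), "node_mass_cost")
  expect_equal(unname(detail["P"]), 0.1)
  expect_equal(unname(detail["GERMLINE"]), 0)  # founder cellularity <= 1
  # divergence satisfied everywhere: zero
  V2 <- rbind(P = c(0.9, 0.9), Q = c(0.4, 0.4), R = c(0.4, 0.4))
  colnames(V2) <- c("s1", "s2")
  expect_equal(as.numeric(mass_cost(tr, V2)), 0)
})

test_that("mass cost equals a literal triple-loop reference on random instances", {
  brute_mc <- function(tree, V) {
    p <- tree$parent
    nodes <- c(GERMLINE, tree$clusters)
    cell <- function(x, s) if (x == GERMLINE) 1 else V[x, s]
    total <- 0
    for (nd in nodes) {
      kids <- tree$clusters[p == nd]
      acc <- 0
      for (s in colnames(V)) {
        ksum <- 0
        for (k in kids) ksum <- ksum + V[k, s]
        acc <- acc + max(0, ksum - cell(nd, s))^2
      }
      total <- total + sqrt(acc)
    }
    total
  }
  set.seed(33)
  for (rep in 1:10) {
    tr <- random_topology(paste0("K", 1:5))
    V <- matrix(runif(15), 5, 3, dimnames = list(paste0("K", 1:5), paste0("s", 1:3)))
    expect_equal(as.numeric(mass_cost(tr, V)), brute_mc(tr, V), tolerance = 1e-12)
  }
})

test_that("fitness is exp(-fc Z) with ~150-fold decay per unit cost", {
  tr <- chain_tree(2)
  cpov0 <- matrix(0, 2, 2, dimnames = list(tr$clusters, tr$clusters))
  sc <- tree_fitness(tr, cpov0, NULL)
  expect_equal(sc$fitness, 1)
  expect_equal(cost_to_fitness(1), exp(-5))
  expect_equal(cost_to_fitness(0) / cost_to_fitness(1), exp(5))
  expect_equal(exp(5), 148.413, tolerance = 1e-4)
  expect_error(tree_fitness(tr, cpov0, NULL, fc = -1), "positive")
})

test_that("true tree has zero cost on noiseless data and is uniquely optimal when branched", {
  tr <- branched5()
  set.seed(44)
  cm <- noiseless_cm(tr, 4)
  cpov <- perfect_cpov(tr)
  expect_equal(topology_cost(tr, cpov), 0)
  expect_equal(as.numeric(mass_cost(tr, cm$value)), 0)
  # over the exhaustive 625, the true tree is the unique fitness-1 topology
  # using the topology cost alone (fully branched CPOV pins the tree)
  all5 <- enumerate_topologies(tr$clusters)
  tc <- vapply(all5, topology_cost, 0, cpov = cpov)
  expect_identical(sum(tc == 0), 1L)
  expect_same_topology(all5[[which(tc == 0)]], tr)
})

test_that("linear chains tie on topology cost and the mass cost breaks the tie", {
  # germline + 4-cluster chain (a 5-node tree counting the root): the CPOV
  # alone leaves 3! = 6 compatible topologies; high cellularities make every
  # wrong attachment violate lineage divergence, so the mass cost singles
  # out the true chain
  tr <- chain_tree(4)
  V <- cbind(S1 = c(1.0, 0.9, 0.8, 0.7), S2 = c(1.0, 0.85, 0.6, 0.5))
  rownames(V) <- tr$clusters
  cpov <- perfect_cpov(tr)
  all4 <- enumerate_topologies(tr$clusters)
  tc <- vapply(all4, topology_cost, 0, cpov = cpov)
  expect_identical(sum(tc == 0), 6L)  # the 6 chain-compatible candidates
  z <- vapply(all4, function(t) tree_fitness(t, cpov, V)$total_cost, 0)
  expect_identical(sum(z == 0), 1L)
  expect_same_topology(all4[[which(z == 0)]], tr)
})

test_that("fitness ranking is invariant under cluster relabeling", {
  set.seed(46)
  labels <- paste0("C", 1:4)
  tr <- random_topology(labels)
  cm <- noiseless_cm(tr, 3, stderr = 0.02)
  cpov <- cluster_cpov(cm)
  all4 <- enumerate_topologies(labels)
  z <- vapply(all4, function(t) tree_fitness(t, cpov, cm$value)$total_cost, 0)
  # permute labels everywhere and recompute
  perm <- setNames(c("X", "Y", "Z", "W"), labels)
  rn <- function(m) { dimnames(m) <- lapply(dimnames(m), function(d) unname(perm[d])); m }
  z_perm <- vapply(all4, function(t) {
    pt <- subclone_tree(setNames(
      ifelse(t$parent == GERMLINE, GERMLINE, perm[t$parent]), perm[t$clusters]))
    tree_fitness(pt, rn(cpov), rn(cm$value))$total_cost
  }, 0)
  expect_equal(z, z_perm, tolerance = 1e-12)
})

test_that("subclone sizes subtract children and telescope to the founder", {
  tr <- subclone_tree(c(A = "GERMLINE", B = "A", C = "A"))
  V <- cbind(S1 = c(A = 1.0, B = 0.6, C = 0.3))
  sz <- subclone_sizes(tr, V)
  expect_equal(sz[, "S1"], c(A = 0.1, B = 0.6, C = 0.3))
  # leaves keep their own cellularity; totals telescope to the founder's
  set.seed(47)
  for (rep in 1:5) {
    t5 <- random_topology(paste0("C", 1:5))
    V5 <- simulate_cellularities(t5, 3)
    sz5 <- subclone_sizes(t5, V5)
    founder <- t5$clusters[t5$parent == GERMLINE]
    expect_equal(colSums(sz5), V5[founder, ], tolerance = 1e-12)
    leaves <- setdiff(t5$clusters, t5$parent)
    expect_equal(sz5[leaves, ], V5[leaves, ])
  }
  # divergence violation clamps with a warning
  bad <- cbind(S1 = c(A = 0.5, B = 0.4, C = 0.3))
  expect_warning(szb <- subclone_sizes(tr, bad), "divergence")
  expect_equal(szb["A", "S1"], 0)
})
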