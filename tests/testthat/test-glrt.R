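test_that("GLRT statistic sums squared z-scores of violated samples only", {
  expect_equal(glrt_statistic(c(0.2, 0.1), c(0.1, 0.1)), 0)
  expect_equal(glrt_statistic(c(-0.1, 0.2, -0.3), c(0.1, 0.1, 0.1)), 10)
  # ties contribute nothing
  expect_equal(glrt_statistic(c(0, 0), c(0.1, 0.1)), 0)
  expect_error(glrt_statistic(c(1, 2), c(0.1, 0)), "positive")
  expect_error(glrt_statistic(1, numeric(0)), "equal-length")
})

test_that("GLRT statistic matches a grid-search likelihood-ratio oracle", {
  grid_T <- function(dhat, sigma) {
    # brute-force maximization of the constrained likelihood on a fine grid
    ratio <- vapply(seq_along(dhat), function(s) {
      d_grid <- seq(0, max(1, dhat[s] + 1), by = 1e-4)
      num <- max(dnorm(dhat[s], d_grid, sigma[s]))
      den <- dnorm(dhat[s], dhat[s], sigma[s])
      num / den
    }, 0)
    -2 * log(prod(ratio))
  }
  set.seed(7)
  for (rep in 1:5) {
    dhat <- runif(5, -0.3, 0.3)
    sigma <- runif(5, 0.05, 0.15)
    expect_equal(glrt_statistic(dhat, sigma), grid_T(dhat, sigma),
                 tolerance = 1e-3)
  }
})

test_that("mixture weights are binomial and sum to one", {
  for (S in c(1, 3, 10, 50)) {
    w <- null_mixture_weights(S)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, choose(S, 0:S) / 2^S)
  }
})

test_that("null tail probability evaluates the chi-square mixture", {
  expect_equal(null_tail_probability(0, 1), 1)
  expect_equal(null_tail_probability(0, 5), 1)
  # S = 1: half point mass at zero, half chi-square_1
  expect_equal(null_tail_probability(qchisq(0.9, 1), 1), 0.05, tolerance = 1e-6)
  # S = 3 at T = 4: direct mixture evaluation
  expected <- (3 * pchisq(4, 1, lower.tail = FALSE) +
               3 * pchisq(4, 2, lower.tail = FALSE) +
               pchisq(4, 3, lower.tail = FALSE)) / 8
  expect_equal(null_tail_probability(4, 3), expected)
  expect_equal(null_tail_probability(4, 3), 0.100, tolerance = 1e-2)
  # non-increasing in T, elementwise on vectors
  p <- null_tail_probability(seq(0, 10, by = 0.25), 4)
  expect_true(all(diff(p) <= 0))
})

test_that("analytic null matches Monte Carlo draws of the statistic at deciles", {
  m <- 1e6
  set.seed(314)
  for (S in c(1, 3, 5)) {
    z <- matrix(rnorm(m * S), m, S)
    T_mc <- rowSums(z^2 * (z < 0))
    for (p0 in seq(0.1, 0.5, by = 0.1)) {
      # analytic upper-tail quantile, then compare empirical tail mass
      C <- uniroot(function(x) null_tail_probability(x, S) - p0,
                   c(0, 50), tol = 1e-9)$root
      emp <- mean(T_mc >= C)
      expect_lt(abs(emp - p0), 3 * sqrt(p0 * (1 - p0) / m))
    }
  }
})

test_that("test is conservative under the composite null and loses power with margin", {
  m <- 20000
  S <- 3
  sigma <- 0.05
  set.seed(99)
  rates <- vapply(c(0, 0.025, 0.05), function(delta) {
    d <- matrix(rnorm(m * S, mean = delta, sd = sigma), m, S)
    T <- rowSums((d / sigma)^2 * (d < 0))
    mean(null_tail_probability(T, S) < 0.05)
  }, 0)
  se <- sqrt(0.05 * 0.95 / m)
  expect_true(all(rates <= 0.05 + 3 * se))
  expect_true(all(diff(rates) < 0))
})

test_that("precedence test fills all components consistently", {
  a <- list(value = c(0.5, 0.5), stderr = c(0.05, 0.05))
  self <- test_precedence(a, a)
  expect_equal(self$statistic, 0)
  expect_equal(self$pvalue, 1)
  expect_false(self$reject)
  # clear ancestor: no rejection
  b <- list(value = c(0.1, 0.2), stderr = c(0.05, 0.05))
  expect_false(test_precedence(a, b)$reject)
  # reversal in one sample
  ci <- list(value = c(0.3, 0.9), stderr = c(0.05, 0.05))
  cj <- list(value = c(0.8, 0.2), stderr = c(0.05, 0.05))
  tt <- test_precedence(ci, cj)
  expect_equal(tt$statistic, 50, tolerance = 1e-9)
  expect_lt(tt$pvalue, 1e-6)
  expect_true(tt$reject)
  expect_equal(tt$statistic, -2 * log(tt$likelihood_ratio), tolerance = 1e-9)
  expect_identical(tt$reject, tt$pvalue < tt$alpha)
  # mismatched samples rejected
  expect_error(test_precedence(a, list(value = 0.1, stderr = 0.05)),
               "same samples")
})

test_that("POV of noiseless data reproduces the topology truth table", {
  tr <- subclone_tree(c(A = "GERMLINE", B = "A", C = "A", D = "B"))
  set.seed(11)
  cm <- noiseless_cm(tr, 6)
  pov <- build_pov(cm, 0.05)
  truth <- truth_pov(tr)
  # guaranteed part: no false rejections of true lineage pairs, zero diagonal
  expect_true(all(pov[truth == 0L] == 0L))
  expect_true(all(diag(pov) == 0L))
  # with 6 samples every non-lineage pair shows a reversal at this seed
  expect_identical(unname(pov), unname(truth))
})

test_that("identical entities yield an all-zero POV", {
  V <- matrix(0.5, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  cm <- cellularity_matrix(V, V * 0 + 0.05)
  expect_true(all(build_pov(cm) == 0L))
})

test_that("vote aggregation averages POV blocks", {
  pov <- matrix(0L, 5, 5, dimnames = list(paste0("m", 1:5), paste0("m", 1:5)))
  assignment <- c(m1 = "I", m2 = "I", m3 = "J", m4 = "J", m5 = "J")
  # 3 of the 6 entries in block I x J rejected
  pov["m1", "m3"] <- 1L; pov["m1", "m4"] <- 1L; pov["m2", "m5"] <- 1L
  cpov <- aggregate_cpov(pov, assignment)
  expect_equal(cpov["I", "J"], 0.5)
  expect_equal(cpov["J", "I"], 0)
  expect_true(all(cpov >= 0 & cpov <= 1))
  # all-zero POV stays all zero; singletons reduce to the POV itself
  expect_true(all(aggregate_cpov(pov * 0L, assignment) == 0))
  singles <- setNames(paste0("K", 1:5), paste0("m", 1:5))
  expect_equal(unname(aggregate_cpov(pov, singles)), unname(pov) + 0)
  expect_error(aggregate_cpov(pov, assignment[-1]), "unassigned")
})

test_that("direct cluster-level CPOV recovers chain order under strong separation", {
  # two clusters, strict dominance
  V <- matrix(c(0.9, 0.8, 0.3, 0.2), 2, 2, byrow = TRUE,
              dimnames = list(c("I", "J"), c("s1", "s2")))
  cm <- cellularity_matrix(V, V * 0 + 0.02)
  cpov <- cluster_cpov(cm)
  expect_identical(unname(cpov), matrix(c(0L, 1L, 0L, 0L), 2))
  # noiseless 5-cluster linear chain: lower triangle ones, upper zeros
  tr <- chain_tree(5)
  set.seed(21)
  cm5 <- noiseless_cm(tr, 8)
  cpov5 <- cluster_cpov(cm5)[tr$clusters, tr$clusters]
  expect_true(all(cpov5[upper.tri(cpov5)] == 0L))
  expect_true(all(cpov5[lower.tri(cpov5)] == 1L))
})
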