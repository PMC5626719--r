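test_that("canonical relabeling is by first appearance, idempotent and invariant", {
  p <- partition(c(2L, 2L, 1L, 3L), K = 3L)
  cp <- canonicalize_partition(p)
  expect_equal(unclass(cp), c(1L, 1L, 2L, 3L), ignore_attr = TRUE)
  expect_identical(canonicalize_partition(cp), cp)
  relab <- partition(c(3L, 3L, 2L, 1L), K = 3L)
  expect_identical(canonicalize_partition(relab), cp)
})

test_that("the Gibbs kernel is greedy at low temperature and uniform at high", {
  gm <- private_block_gm(n_per_group = 4, n_loci = 20)
  z <- c(2L, rep(1L, 3L), rep(2L, 4L))           # individual 1 misassigned
  part <- partition(z, K = 2L)
  ct <- build_counts(gm, part)
  # T -> 0+: the LR-maximizing label is chosen essentially surely
  set.seed(1)
  res <- gibbs_step(gm, ct, part, r = 1L, temperature = 1e-8)
  expect_equal(res$chosen, 1L)
  expect_gt(res$delta, 0)
  # T -> Inf: labels drawn uniformly (chi-square GOF on 10,000 draws)
  set.seed(2)
  draws <- replicate(10000, gibbs_step(gm, ct, part, 1L, 1e12)$chosen)
  expect_gt(stats::chisq.test(tabulate(draws, 2L))$p.value, 0.01)
  # K = 1: nothing can change
  ct1 <- build_counts(gm, partition(rep(1L, 8), K = 1L))
  res1 <- gibbs_step(gm, ct1, partition(rep(1L, 8), K = 1L), 3L, 1)
  expect_equal(res1$chosen, 1L)
  expect_equal(res1$delta, 0)
})

test_that("annealing attains the brute-force optimum on a separable dataset", {
  gm <- private_block_gm(n_per_group = 4, n_loci = 50)
  res <- anneal(gm, K = 2, schedule = test_schedule(), seed = 5, restarts = 5)
  expect_equal(res$best_lr, brute_force_best_lr_k2(gm), tolerance = 1e-9)
  expect_equal(unclass(res$best_partition),
               rep(1:2, each = 4), ignore_attr = TRUE)
})

test_that("anneal results are exactly reproducible from the seed", {
  sim <- simulate_genotypes(K = 3, sizes = rep(20L, 3), n_loci = 150,
                            F = 0.08, seed = 41)
  a <- anneal(sim$genotypes, K = 3, schedule = test_schedule(), seed = 99,
              restarts = 3)
  b <- anneal(sim$genotypes, K = 3, schedule = test_schedule(), seed = 99,
              restarts = 3)
  expect_identical(a, b)
})

test_that("reported LR matches a from-scratch rebuild and the trace is monotone", {
  sim <- simulate_genotypes(K = 3, sizes = rep(15L, 3), n_loci = 120,
                            F = 0.08, missing_rate = 0.05, seed = 43)
  res <- anneal(sim$genotypes, K = 3, schedule = test_schedule(), seed = 7,
                restarts = 2)
  expect_equal(res$best_lr, total_lr(sim$genotypes, res$best_partition),
               tolerance = 1e-6)
  expect_true(all(diff(res$lr_trace) >= -1e-9))
})

test_that("K = 1 yields the trivial partition with zero LR", {
  gm <- random_gm(6, 20, seed = 47)
  res <- anneal(gm, K = 1, seed = 1)
  expect_equal(res$best_lr, 0)
  expect_equal(unclass(res$best_partition), rep(1L, 6), ignore_attr = TRUE)
})

test_that("unused groups are allowed and reported with a warning", {
  # K exceeds N, so at least one group must stay empty
  gm <- private_block_gm(n_per_group = 2, n_loci = 40)
  w <- capture_warnings(
    res <- anneal(gm, K = 5, schedule = test_schedule(), seed = 3,
                  restarts = 2))
  expect_true(any(grepl("occupied", w)))
  expect_lt(res$n_nonempty_groups, 5L)
})

test_that("accuracy is non-decreasing as independent loci are added", {
  ari_at <- function(s) {
    mean(vapply(1:2, function(rep) {
      sim <- simulate_genotypes(K = 3, sizes = rep(30L, 3), n_loci = s,
                                F = 0.01, seed = 100 + rep)
      res <- anneal(sim$genotypes, K = 3, schedule = test_schedule(),
                    seed = rep, restarts = 3)
      adjusted_rand_index(sim$truth, res$best_partition)
    }, numeric(1)))
  }
  aris <- vapply(c(100L, 400L, 1600L), ari_at, numeric(1))
  expect_true(all(diff(aris) >= -0.02))
  expect_gt(aris[3], 0.9)
})
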