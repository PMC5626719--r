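test_that("the generator is reproducible and validates its parameters", {
  a <- simulate_genotypes(K = 2, sizes = c(5L, 5L), n_loci = 20, F = 0.05,
                          seed = 71)
  b <- simulate_genotypes(K = 2, sizes = c(5L, 5L), n_loci = 20, F = 0.05,
                          seed = 71)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(unclass(a$truth), unclass(b$truth))
  expect_error(simulate_genotypes(K = 2, sizes = 5L, n_loci = 10), "sizes")
  expect_error(simulate_genotypes(K = 2, sizes = c(5L, 5L), n_loci = 10,
                                  F = 1.2), "F")
})

test_that("ancestral frequencies respect the truncation range", {
  sim <- simulate_genotypes(K = 1, sizes = 2000L, n_loci = 300, F = 0,
                            seed = 73)
  p_hat <- colMeans(sim$genotypes$calls[, , 1] + sim$genotypes$calls[, , 2]) / 2
  # under panmixia the sample frequency tracks the ancestral one closely
  expect_true(all(p_hat > 0.01 & p_hat < 0.99))
  expect_gt(diff(range(p_hat)), 0.5)            # spread across the range
})

test_that("missingness is injected at the requested rate", {
  sim <- simulate_genotypes(K = 1, sizes = 200L, n_loci = 100, F = 0,
                            missing_rate = 0.1, seed = 79)
  expect_lt(abs(mean(is.na(sim$genotypes$calls)) - 0.1), 0.01)
})

test_that("split-tree drift produces nested divergence", {
  sim <- simulate_genotypes(K = 4, sizes = rep(100L, 4), n_loci = 1500,
                            F = 0.04, model = "split_tree", seed = 83)
  z <- unclass(sim$truth)
  fst_pair <- function(i, j) {
    sel <- z %in% c(i, j)
    gsub <- genotype_matrix(sim$genotypes$calls[sel, , , drop = FALSE],
                            n_alleles = 2L)
    objective_fst(gsub, partition(match(z[sel], c(i, j)), K = 2L))
  }
  # sisters (1,2) and (3,4) are closer than cross-clade pairs
  expect_lt(fst_pair(1, 2), fst_pair(1, 3))
  expect_lt(fst_pair(3, 4), fst_pair(1, 4))
})

test_that("adjusted Rand index matches its defining properties and mclust", {
  z <- sample.int(4, 200, TRUE)
  expect_equal(adjusted_rand_index(z, z), 1)
  relab <- c(4L, 3L, 2L, 1L)[z]
  expect_equal(adjusted_rand_index(z, relab), 1)
  set.seed(87)
  a <- sample.int(3, 10000, TRUE)
  b <- sample.int(3, 10000, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.01)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
  skip_if_not_installed("mclust")
  for (i in 1:10) {
    x <- sample.int(4, 50, TRUE)
    y <- sample.int(3, 50, TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("confusion tables count, name by majority, and score concordance", {
  z <- c(1L, 1L, 2L, 2L)
  tab <- confusion_table(z, c("A", "A", "B", "B"))
  expect_equal(attr(tab, "cluster_names"), c("A", "B"), ignore_attr = TRUE)
  expect_equal(unclass(tab)[, c("A", "B")], matrix(c(2L, 0L, 0L, 2L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(tab), 4)
  expect_equal(concordance(tab), 1)
  # one mixed cluster: [[1,1],[0,0]] named by lexicographic majority "A"
  m <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
              dimnames = list(NULL, c("A", "B")))
  expect_equal(concordance(as_confusion_table(m)), 0.5)
  expect_error(concordance(tab, exclude_labels = c("A", "B")), "excluded")
})

test_that("clusters recover the simulated subpopulations end to end", {
  sim <- simulate_genotypes(K = 3, sizes = rep(25L, 3), n_loci = 400,
                            F = 0.05, seed = 91)
  res <- anneal(sim$genotypes, K = 3, schedule = test_schedule(), seed = 2,
                restarts = 3)
  expect_gte(adjusted_rand_index(sim$truth, res$best_partition), 0.95)
  labels <- LETTERS[unclass(sim$truth)]
  tab <- confusion_table(res$best_partition, labels)
  expect_gte(concordance(tab), 0.95)
})

test_that("the published 11,257-genome confusion table loads with its marginals", {
  tab <- wgs11257_confusion()
  expect_equal(dim(tab), c(6L, 7L))
  expect_identical(sort(attr(tab, "cluster_names")),
                   sort(c("EAS", "AFR", "CSA", "MDE", "AMR", "EUR")))
  expect_equal(sum(tab[, "ADMIX"]), 2385)
  expect_equal(sum(tab), 11257)
})
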