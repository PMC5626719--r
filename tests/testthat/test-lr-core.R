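test_that("locus_lr matches hand-evaluated tables", {
  expect_equal(locus_lr(matrix(5, 2, 2)), 0)
  expect_equal(locus_lr(matrix(c(10, 0, 0, 10), 2, 2)), 20 * log(2),
               tolerance = 1e-12)
  expect_equal(locus_lr(matrix(c(7, 3), nrow = 1)), 0)   # one group: E = O
  expect_equal(locus_lr(matrix(0, 3, 2)), 0)             # empty table
  expect_error(locus_lr(matrix(c(-1, 1, 1, 1), 2, 2)), "negative")
})

test_that("an all-zero row (empty group) contributes nothing", {
  tab <- matrix(c(4, 1, 0, 0, 2, 7), nrow = 3, byrow = TRUE)
  expect_equal(locus_lr(tab), locus_lr(tab[-2, , drop = FALSE]))
})

test_that("twice locus_lr equals the G-statistic from loglin on random tables", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(2:4, 1)
    tab <- matrix(rpois(k * n, lambda = 8), k, n)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    g <- stats::loglin(tab, margin = list(1, 2), fit = FALSE, print = FALSE)$lrt
    expect_equal(2 * locus_lr(tab), g, tolerance = 1e-9)
  }
})

test_that("locus_lr is non-negative and zero iff rows are proportional to column totals", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(6, 5), 2, 3)
    expect_gte(locus_lr(tab), -1e-12)
  }
  prop <- rbind(2 * c(3, 1, 6), 5 * c(3, 1, 6))   # rows proportional
  expect_equal(locus_lr(prop), 0, tolerance = 1e-12)
})

test_that("build_counts tallies allele calls per group with missing skipped", {
  calls <- array(c(0L, 1L, 0L, 1L), dim = c(2, 1, 2))
  gm <- genotype_matrix(calls, n_alleles = 2L)   # genotypes 0/0 and 1/1
  ct <- build_counts(gm, partition(c(1L, 2L), K = 2L))
  expect_equal(ct$tables[[1]], matrix(c(2, 0, 0, 2), 2, 2))
  ct1 <- build_counts(gm, partition(c(1L, 1L), K = 2L))
  expect_equal(ct1$tables[[1]], matrix(c(2, 2, 0, 0), 2, 2, byrow = TRUE))
  gm$calls[1, 1, 2] <- NA_integer_               # one call missing
  ct2 <- build_counts(gm, partition(c(1L, 2L), K = 2L))
  expect_equal(ct2$grand, 3)
  expect_error(build_counts(gm, partition(1L, K = 1L)), "length")
})

test_that("total_lr is additive over loci and zero for one group", {
  gm <- random_gm(10, 8, seed = 5)
  one <- subset_loci(gm, 1L)
  two <- genotype_matrix(gm$calls[, c(1, 1), , drop = FALSE],
                         n_alleles = gm$n_alleles[c(1, 1)])
  part <- partition(rep(1:2, 5), K = 2L)
  expect_equal(total_lr(two, part), 2 * total_lr(one, part), tolerance = 1e-12)
  expect_equal(total_lr(gm, partition(rep(1L, 10), K = 1L)), 0)
})

test_that("total_lr equals the sum of independent per-locus evaluations", {
  gm <- random_gm(30, 500, n_alleles = sample(2:3, 500, TRUE),
                  missing_rate = 0.05, seed = 11)
  part <- partition(sample.int(3, 30, TRUE), K = 3L)
  ct <- build_counts(gm, part)
  by_locus <- sum(vapply(seq_len(500), function(s) locus_lr(ct$tables[[s]]),
                         numeric(1)))
  expect_equal(total_lr(ct), by_locus, tolerance = 1e-9)
})

test_that("total_lr is invariant under group relabeling and locus reordering", {
  gm <- random_gm(12, 40, missing_rate = 0.1, seed = 13)
  z <- sample.int(3, 12, TRUE)
  perm <- c(3L, 1L, 2L)
  lr1 <- total_lr(gm, partition(z, K = 3L))
  lr2 <- total_lr(gm, partition(perm[z], K = 3L))
  expect_equal(lr1, lr2, tolerance = 1e-9)
  ord <- sample.int(40)
  expect_equal(total_lr(subset_loci(gm, ord), partition(z, K = 3L)), lr1,
               tolerance = 1e-9)
})

test_that("delta_lr_move agrees with full recomputation and reverses exactly", {
  gm <- random_gm(15, 60, n_alleles = sample(2:3, 60, TRUE),
                  missing_rate = 0.1, seed = 17)
  z <- sample.int(4, 15, TRUE)
  part <- partition(z, K = 4L)
  ct <- build_counts(gm, part)
  lr <- total_lr(ct)
  set.seed(18)
  for (i in 1:200) {
    r <- sample.int(15, 1)
    to <- sample.int(4, 1)
    ci <- individual_calls(gm, r)
    d <- delta_lr_move(ct, ci, z[r], to)
    z2 <- z; z2[r] <- to
    expect_equal(d, total_lr(gm, partition(z2, K = 4L)) - lr,
                 tolerance = 1e-8)
    # reversibility without mutation
    ct_moved <- apply_move(ct, ci, z[r], to)
    d_back <- delta_lr_move(ct_moved, ci, to, z[r])
    expect_equal(d + d_back, 0, tolerance = 1e-8)
  }
  expect_equal(delta_lr_move(ct, individual_calls(gm, 1), 2L, 2L), 0)
  expect_error(delta_lr_move(ct, individual_calls(gm, 1), 1L, 9L), "range")
})

test_that("apply_move keeps cached state identical to a rebuild", {
  gm <- random_gm(12, 30, missing_rate = 0.2, seed = 23)
  z <- sample.int(3, 12, TRUE)
  ct <- build_counts(gm, partition(z, K = 3L))
  set.seed(24)
  for (i in 1:50) {
    r <- sample.int(12, 1)
    to <- sample.int(3, 1)
    ct <- apply_move(ct, individual_calls(gm, r), z[r], to)
    z[r] <- to
  }
  fresh <- build_counts(gm, partition(z, K = 3L))
  expect_identical(lapply(ct$tables, unname), lapply(fresh$tables, unname))
  expect_equal(ct$row_totals, fresh$row_totals)
  expect_equal(ct$grand, fresh$grand)           # grand totals conserved
})

test_that("DAF matches hand frequencies and refuses more than two groups", {
  # group freqs 0.8 vs 0.2 at one locus: 5 individuals per group
  calls <- array(NA_integer_, dim = c(10, 1, 2))
  calls[1:5, 1, ] <- cbind(c(1L, 1L, 1L, 1L, 0L), c(1L, 1L, 1L, 1L, 0L))
  calls[6:10, 1, ] <- cbind(c(0L, 0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L, 1L))
  gm <- genotype_matrix(calls, n_alleles = 2L)
  part <- partition(rep(1:2, each = 5), K = 2L)
  expect_equal(objective_daf(gm, part), 0.6, tolerance = 1e-12)
  # identical group frequencies => 0
  sym <- genotype_matrix(array(rep(c(0L, 1L), each = 4), c(4, 1, 2)),
                         n_alleles = 2L)
  expect_equal(objective_daf(sym, partition(c(1L, 2L, 1L, 2L), K = 2L)), 0)
  expect_error(objective_daf(gm, partition(c(rep(1:2, each = 4), 3L, 3L), K = 3L)),
               "K = 2")
})

test_that("Hudson Fst is 1 at fixation, near 0 under panmixia, near F under drift", {
  fixed <- private_block_gm(n_per_group = 20, n_loci = 10)
  part <- partition(rep(1:2, each = 20), K = 2L)
  expect_equal(objective_fst(fixed, part), 1, tolerance = 1e-12)

  pan <- simulate_genotypes(K = 2, sizes = c(250L, 250L), n_loci = 1000,
                            F = 0, seed = 31)
  expect_lt(abs(objective_fst(pan$genotypes, pan$truth)), 0.02)

  bn <- simulate_genotypes(K = 2, sizes = c(200L, 200L), n_loci = 2000,
                           F = 0.05, seed = 37)
  est <- objective_fst(bn$genotypes, bn$truth)
  expect_gt(est, 0.03)
  expect_lt(est, 0.07)
})
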