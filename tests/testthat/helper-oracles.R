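# small random genotype datasets and brute-force references used across tests

# random diploid genotype matrix with arbitrary allele counts and optional
# missingness; codes drawn uniformly so tables are unstructured
random_gm <- function(n, s, n_alleles = 2L, missing_rate = 0, seed = 1L) {
  set.seed(seed)
  n_alleles <- rep_len(n_alleles, s)
  calls <- array(NA_integer_, dim = c(n, s, 2L))
  for (loc in seq_len(s)) {
    x <- sample.int(n_alleles[loc], n * 2L, replace = TRUE) - 1L
    if (missing_rate > 0) x[runif(n * 2L) < missing_rate] <- NA_integer_
    calls[, loc, ] <- x
  }
  genotype_matrix(calls, n_alleles = n_alleles)
}

# exhaustive maximum of the total LR over all bipartitions (K = 2); label
# switching halved by fixing individual 1 in group 1
brute_force_best_lr_k2 <- function(gm) {
  n <- n_individuals(gm)
  stopifnot(n <= 16L)
  best <- -Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    z <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1L)] + 1L)
    lr <- total_lr(gm, partition(z, K = 2L))
    if (lr > best) best <- lr
  }
  best
}

# two-population dataset with private-allele blocks: the first half of the
# loci are fixed 0/0 in group A and 1/1 in group B, the rest vice versa
private_block_gm <- function(n_per_group = 4L, n_loci = 50L) {
  n <- 2L * n_per_group
  calls <- array(0L, dim = c(n, n_loci, 2L))
  grp_b <- (n_per_group + 1L):n
  first <- seq_len(n_loci %/% 2L)
  calls[grp_b, first, ] <- 1L
  calls[seq_len(n_per_group), setdiff(seq_len(n_loci), first), ] <- 1L
  genotype_matrix(calls, n_alleles = 2L)
}

# schedule small enough for test-suite datasets; converges reliably there
test_schedule <- function(n_epochs = 40L, greedy_epochs = 20L) {
  cooling_schedule(n_epochs = n_epochs, greedy_epochs = greedy_epochs)
}

# write a small VCF fixture; body_rows is a character vector of data lines
write_test_vcf <- function(path, body_rows,
                           samples = c("s1", "s2", "s3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_rows), path)
  path
}
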