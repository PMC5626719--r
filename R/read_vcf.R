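#' Read diploid genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file (plain or bgzipped) into a
#' [genotype_matrix()]. Phase separators (`|`) are treated identically to
#' `/` — phase carries no information for the allele-count objective. A `.`
#' component maps to a missing call, so a half-called genotype like `1/.`
#' keeps its one observed allele.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file with GT fields.
#' @param min_allele_count drop a locus unless at least one non-reference
#'   allele is observed in `>= min_allele_count` copies (0 keeps everything,
#'   1 drops loci monomorphic for the reference).
#' @param biallelic_only drop records with more than one ALT allele.
#' @return a [genotype_matrix()] with one locus per retained VCF record;
#'   `n_alleles[s]` is the record's declared allele count (1 + number of ALT
#'   alleles), so every call code is `< n_alleles[s]`.
#' @export
read_vcf <- function(path, min_allele_count = 1L, biallelic_only = FALSE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  min_allele_count <- as.integer(min_allele_count)
  if (min_allele_count < 0L) stop("'min_allele_count' must be >= 0")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n_rec <- nrow(vcf@fix)
  if (is.null(n_rec) || n_rec == 0L) stop("VCF contains no records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  alt <- vcf@fix[, "ALT"]
  n_alt <- ifelse(is.na(alt) | alt == "." | alt == "",
                  0L, lengths(strsplit(alt, ",", fixed = TRUE)))
  ids <- vcf@fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(vcf@fix[no_id, "CHROM"], ":", vcf@fix[no_id, "POS"])
  ids <- make.unique(ids)

  toks <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
  if (any(lengths(toks) != 2L & !is.na(gt)))
    stop("malformed GT: expected diploid 'a/b' or 'a|b' calls")
  toks[is.na(gt)] <- list(c(".", "."))
  tok <- unlist(toks, use.names = FALSE)
  ok <- tok == "." | grepl("^[0-9]+$", tok)
  if (!all(ok)) stop("malformed GT token(s): ",
                     paste(unique(tok[!ok])[1:5], collapse = ", "))
  code <- ifelse(tok == ".", NA_integer_, suppressWarnings(as.integer(tok)))
  # gt is loci x individuals; tokens run ploidy-fastest, then locus, then ind
  n_ind <- ncol(gt)
  arr <- array(code, dim = c(2L, n_rec, n_ind))
  calls <- aperm(arr, c(3L, 2L, 1L))

  maxcode <- apply(calls, 2L, function(x) {
    suppressWarnings(max(c(x, 0L), na.rm = TRUE))
  })
  over <- maxcode > n_alt
  if (any(over))
    stop("GT allele index exceeds the declared ALT count at ",
         sum(over), " record(s)")

  keep_bi <- if (biallelic_only) n_alt == 1L else rep(TRUE, n_rec)
  mac <- vapply(seq_len(n_rec), function(s) {
    x <- calls[, s, ]
    x <- x[!is.na(x) & x > 0L]
    if (!length(x)) 0L else max(tabulate(x, nbins = max(1L, n_alt[s])))
  }, integer(1L))
  keep_mac <- mac >= min_allele_count
  keep <- keep_bi & keep_mac
  if (!any(keep))
    stop(sprintf(
      "no loci left after filtering (%d of %d failed biallelic_only, %d of %d below min_allele_count=%d)",
      sum(!keep_bi), n_rec, sum(!keep_mac), n_rec, min_allele_count))
  genotype_matrix(calls[, keep, , drop = FALSE],
                  individual_ids = colnames(gt),
                  locus_ids = ids[keep],
                  n_alleles = pmax(n_alt[keep] + 1L, 1L))
}

#' Greedy windowed LD pruning
#'
#' Plink-style pruning of linked loci on the squared Pearson correlation of
#' allele-1 dosages. Within each window of `window` consecutive loci, pairs
#' are scanned left to right and the later locus of any pair with
#' `r^2 > r2_max` is removed; the window then slides by `step` loci. Pairs
#' with missing dosages use pairwise-complete observations; a pair with no
#' complete observations, or with a monomorphic member, is never pruned.
#' Non-biallelic loci are passed through untouched and reported via the
#' `non_biallelic` attribute.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_max squared-correlation threshold in `[0, 1]`; `1` retains
#'   everything.
#' @param window window width in loci (`>= step`).
#' @param step slide of the window in loci.
#' @return strictly increasing integer vector of retained locus indices, with
#'   attribute `non_biallelic` flagging indices retained only because they
#'   are not biallelic.
#' @export
ld_prune <- function(gm, r2_max = 0.2, window = 50L, step = 5L) {
  if (!is.numeric(r2_max) || length(r2_max) != 1L || r2_max < 0 || r2_max > 1)
    stop("'r2_max' must be a number in [0, 1]")
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L || window < step)
    stop("need window >= step >= 1")
  s <- n_loci(gm)
  biallelic <- gm$n_alleles == 2L
  d <- dosage_matrix(gm)
  removed <- rep(FALSE, s)
  starts <- unique(c(seq(1L, max(1L, s - 1L), by = step)))
  for (w0 in starts) {
    w1 <- min(w0 + window - 1L, s)
    idx <- (w0:w1)[biallelic[w0:w1] & !removed[w0:w1]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(
      stats::cor(d[, idx, drop = FALSE], use = "pairwise.complete.obs"))^2
    for (a in seq_along(idx)[-length(idx)]) {
      if (removed[idx[a]]) next
      for (b in (a + 1L):length(idx)) {
        if (removed[idx[b]]) next
        if (!is.na(r2[a, b]) && r2[a, b] > r2_max) removed[idx[b]] <- TRUE
      }
    }
    if (w1 == s) break
  }
  kept <- which(!removed)
  structure(kept, non_biallelic = kept[!biallelic[kept]])
}
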