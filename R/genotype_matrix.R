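#' Genotype matrix container
#'
#' An in-memory container for multi-individual genotype calls at unlinked
#' polymorphic loci. Calls are stored as a 3-dimensional integer array
#' (individuals x loci x ploidy) of 0-based allele codes, with `NA` marking a
#' missing allele call. Phase carries no information for any method in this
#' package, so the order of calls within an individual/locus is arbitrary.
#'
#' @param calls integer array of dimension `N x S x ploidy`; 0-based allele
#'   codes, `NA` for missing calls.
#' @param individual_ids character vector of `N` unique individual ids.
#' @param locus_ids character vector of `S` unique locus ids.
#' @param n_alleles optional integer vector giving the number of allele states
#'   at each locus. Defaults to `1 + max(observed code)` per locus (at least 1).
#' @return An object of class `genotype_matrix` with fields `calls`,
#'   `individual_ids`, `locus_ids`, `ploidy`, `n_alleles`.
#' @export
genotype_matrix <- function(calls, individual_ids = NULL, locus_ids = NULL,
                            n_alleles = NULL) {
  if (!is.array(calls) || length(dim(calls)) != 3L)
    stop("'calls' must be a 3-d array (individuals x loci x ploidy)")
  storage.mode(calls) <- "integer"
  n <- dim(calls)[1L]
  s <- dim(calls)[2L]
  ploidy <- dim(calls)[3L]
  if (n < 1L || s < 1L || ploidy < 1L)
    stop("genotype matrix needs at least one individual, locus and call slot")
  if (any(calls < 0L, na.rm = TRUE))
    stop("allele codes must be non-negative")
  if (is.null(individual_ids))
    individual_ids <- paste0("ind_", seq_len(n))
  if (is.null(locus_ids))
    locus_ids <- paste0("locus_", seq_len(s))
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (length(individual_ids) != n || anyDuplicated(individual_ids))
    stop("'individual_ids' must be ", n, " unique strings")
  if (length(locus_ids) != s || anyDuplicated(locus_ids))
    stop("'locus_ids' must be ", s, " unique strings")
  max_code <- apply(calls, 2L, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  max_code[!is.finite(max_code)] <- 0L
  if (is.null(n_alleles)) {
    n_alleles <- as.integer(max_code + 1L)
  } else {
    n_alleles <- as.integer(n_alleles)
    if (length(n_alleles) == 1L) n_alleles <- rep(n_alleles, s)
    if (length(n_alleles) != s || any(n_alleles < 1L))
      stop("'n_alleles' must be a positive integer per locus")
    if (any(max_code + 1L > n_alleles))
      stop("observed allele code exceeds declared n_alleles")
  }
  structure(
    list(calls = calls, individual_ids = individual_ids,
         locus_ids = locus_ids, ploidy = ploidy, n_alleles = n_alleles),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci, ploidy %d\n",
    n_individuals(x), n_loci(x), x$ploidy))
  cat(sprintf("  allele states per locus: %d-%d; missing calls: %.2f%%\n",
              min(x$n_alleles), max(x$n_alleles), 100 * miss))
  invisible(x)
}

#' Number of individuals / loci
#' @param gm a [genotype_matrix()].
#' @return an integer.
#' @export
n_individuals <- function(gm) dim(gm$calls)[1L]

#' @rdname n_individuals
#' @export
n_loci <- function(gm) dim(gm$calls)[2L]

#' Subset a genotype matrix by locus
#' @param gm a [genotype_matrix()].
#' @param loci integer indices of loci to keep.
#' @return a [genotype_matrix()] restricted to `loci`.
#' @export
subset_loci <- function(gm, loci) {
  loci <- as.integer(loci)
  if (any(loci < 1L | loci > n_loci(gm))) stop("locus index out of range")
  genotype_matrix(gm$calls[, loci, , drop = FALSE],
                  gm$individual_ids, gm$locus_ids[loci],
                  n_alleles = gm$n_alleles[loci])
}

#' Per-locus calls of one individual
#'
#' @param gm a [genotype_matrix()].
#' @param i individual index.
#' @return an `S x ploidy` integer matrix of that individual's allele codes.
#' @export
individual_calls <- function(gm, i) {
  m <- gm$calls[i, , , drop = FALSE]
  dim(m) <- dim(gm$calls)[2:3]
  m
}

#' Allele-1 dosage matrix
#'
#' Number of copies of the allele coded 1 per individual and locus, for
#' biallelic loci. An individual's dosage is `NA` wherever any of its calls
#' at that locus is missing. Non-biallelic loci yield `NA` columns.
#'
#' @param gm a [genotype_matrix()].
#' @return `N x S` integer matrix of dosages in `0..ploidy`.
#' @export
dosage_matrix <- function(gm) {
  d <- apply(gm$calls, c(1L, 2L), function(x) {
    if (anyNA(x)) NA_integer_ else sum(x == 1L)
  })
  d[, gm$n_alleles > 2L] <- NA_integer_
  dimnames(d) <- list(gm$individual_ids, gm$locus_ids)
  d
}

# internal: flatten calls to the N x (S*ploidy) layout used by the C++ core
# (locus-major: columns (s-1)*ploidy + 1..ploidy).
flat_calls <- function(gm) {
  d <- dim(gm$calls)
  m <- aperm(gm$calls, c(1L, 3L, 2L))
  dim(m) <- c(d[1L], d[2L] * d[3L])
  storage.mode(m) <- "integer"
  m
}

#' Read a tab-delimited genotype matrix
#'
#' The plain-text interchange format: a UTF-8 TSV whose header row is `id`
#' followed by the locus ids; each subsequent row is an individual id followed
#' by one cell per locus. A cell is `ploidy` integer allele codes joined by
#' `/` (e.g. `0/1`), with `.` for a missing call (`./.` fully missing).
#'
#' @param path path to the TSV file.
#' @return a [genotype_matrix()]; `n_alleles[s]` is `1 + max(observed code)`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genotype file needs a header and >= 1 individual")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("header must be 'id' followed by locus ids")
  locus_ids <- header[-1L]
  s <- length(locus_ids)
  body <- fields[-1L]
  bad <- which(lengths(body) != s + 1L)
  if (length(bad))
    stop("ragged row(s) at line(s) ", paste(bad + 1L, collapse = ", "))
  individual_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  toks <- strsplit(cells, "/", fixed = TRUE)
  ploidy <- length(toks[[1L]])
  if (any(lengths(toks) != ploidy))
    stop("inconsistent ploidy: all cells must have ", ploidy, " '/'-separated calls")
  tok <- unlist(toks, use.names = FALSE)
  is_miss <- tok == "."
  ok <- is_miss | grepl("^[0-9]+$", tok)
  if (!all(ok))
    stop("non-integer allele token(s): ", paste(unique(tok[!ok])[1:5], collapse = ", "))
  code <- rep(NA_integer_, length(tok))
  code[!is_miss] <- as.integer(tok[!is_miss])
  # cells are row-major over individuals, then loci, then ploidy slots
  arr <- array(code, dim = c(ploidy, s, length(body)))
  calls <- aperm(arr, c(3L, 2L, 1L))
  genotype_matrix(calls, individual_ids, locus_ids)
}

#' Write a genotype matrix to the tab-delimited format
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly. `read_matrix(write_matrix(gm))` reproduces the
#'   calls exactly, including missingness.
#' @export
write_matrix <- function(gm, path) {
  d <- dim(gm$calls)
  tok <- as.character(gm$calls)
  tok[is.na(tok)] <- "."
  dim(tok) <- d
  cells <- apply(tok, c(1L, 2L), paste, collapse = "/")
  rows <- c(paste(c("id", gm$locus_ids), collapse = "\t"),
            paste(gm$individual_ids,
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
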