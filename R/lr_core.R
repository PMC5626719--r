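# x*log(x) with the 0*log(0) := 0 convention used throughout the objective
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Per-locus allele-count-by-group contingency tables
#'
#' Builds the `K x n_alleles[s]` observed-count table at every locus for a
#' given partition: cell `[k, i]` counts the non-missing allele calls equal to
#' allele `i - 1` among individuals assigned to group `k`. Row totals, column
#' totals and grand totals are cached so single-individual moves can be
#' applied and scored incrementally.
#'
#' @param gm a [genotype_matrix()].
#' @param part a [partition()] (or label vector) of length `n_individuals(gm)`.
#' @return an object of class `count_tables`: list with `tables` (list of S
#'   `K x n` matrices), `row_totals` (`K x S`), `col_totals` (list of length-n
#'   vectors), `grand` (length S), `K`, `n_alleles`.
#' @export
build_counts <- function(gm, part) {
  part <- as_partition(part)
  if (length(part) != n_individuals(gm))
    stop("partition length must equal the number of individuals")
  K <- n_groups(part)
  z <- unclass(part)
  s_all <- n_loci(gm)
  ploidy <- gm$ploidy
  zrep <- rep(z, times = ploidy)
  tables <- vector("list", s_all)
  row_totals <- matrix(0, nrow = K, ncol = s_all)
  col_totals <- vector("list", s_all)
  grand <- numeric(s_all)
  for (s in seq_len(s_all)) {
    a <- as.vector(gm$calls[, s, ])
    n_s <- gm$n_alleles[s]
    keep <- !is.na(a)
    tab <- matrix(0, nrow = K, ncol = n_s)
    if (any(keep)) {
      idx <- (zrep[keep] - 1L) * n_s + a[keep] + 1L
      tab <- matrix(tabulate(idx, nbins = K * n_s),
                    nrow = K, ncol = n_s, byrow = TRUE)
    }
    tables[[s]] <- tab
    row_totals[, s] <- rowSums(tab)
    col_totals[[s]] <- colSums(tab)
    grand[s] <- sum(tab)
  }
  structure(list(tables = tables, row_totals = row_totals,
                 col_totals = col_totals, grand = grand,
                 K = K, n_alleles = gm$n_alleles),
            class = "count_tables")
}

#' @export
print.count_tables <- function(x, ...) {
  cat(sprintf("count_tables: %d loci, K = %d groups, %g-%g calls per locus\n",
              length(x$tables), x$K, min(x$grand), max(x$grand)))
  invisible(x)
}

#' Likelihood ratio of one contingency table
#'
#' The per-locus objective: for an observed `K x n` allele-count table `O`
#' with expected counts under independence
#' `E[k, i] = rowsum_k * colsum_i / grand`, returns
#' `sum(O * log(O / E))` in nats. Cells with `O = 0` contribute 0, so the
#' value is finite for any non-negative table; an empty table returns 0.
#' Twice this value is the classical G-statistic of the table.
#'
#' @param table non-negative numeric matrix of allele counts (groups x alleles).
#' @return the likelihood ratio in nats (`>= 0` up to rounding).
#' @export
locus_lr <- function(table) {
  o <- as.matrix(table)
  if (any(o < 0)) stop("negative counts")
  g <- sum(o)
  if (g == 0) return(0)
  r <- rowSums(o)
  cs <- colSums(o)
  # sum O log O - sum_k R log R - sum_i C log C + G log G
  sum(xlogx(o)) - sum(xlogx(r)) - sum(xlogx(cs)) + xlogx(g)
}

#' Total likelihood ratio over loci
#'
#' The full objective maximized by the partition search: the sum of
#' [locus_lr()] over all loci, treating loci as independent (hence the
#' recommendation to LD-prune first, see [ld_prune()]).
#'
#' @param x a `count_tables` object from [build_counts()], or a
#'   [genotype_matrix()] (then `part` is required).
#' @param part a [partition()], used when `x` is a genotype matrix.
#' @return total likelihood ratio in nats.
#' @export
total_lr <- function(x, part = NULL) {
  if (inherits(x, "genotype_matrix")) x <- build_counts(x, part)
  if (!inherits(x, "count_tables")) stop("'x' must be count_tables or genotype_matrix")
  sum(vapply(x$tables, locus_lr, numeric(1L)))
}

# shared bookkeeping for a single-individual move: per-locus allele counts the
# individual contributes, restricted to loci with >= 1 non-missing call
move_touch <- function(counts, calls_ind) {
  if (is.null(dim(calls_ind))) calls_ind <- matrix(calls_ind, ncol = 1L)
  loci <- which(rowSums(!is.na(calls_ind)) > 0L)
  lapply(loci, function(s) {
    a <- calls_ind[s, ]
    a <- a[!is.na(a)]
    cnt <- tabulate(a + 1L, nbins = counts$n_alleles[s])
    list(s = s, alleles = which(cnt > 0L) - 1L,
         cnt = cnt[cnt > 0L], m = length(a))
  })
}

#' Objective change of a single-individual move
#'
#' Returns `total_lr(after) - total_lr(before)` for moving one individual
#' from `from_group` to `to_group`, without mutating `counts`. Only loci
#' where the individual has at least one non-missing call contribute, and for
#' each such locus only the two affected rows' terms are recomputed (column
#' totals and grand totals are unchanged by any move), so the cost is
#' `O(S * ploidy)` rather than a full rebuild.
#'
#' @param counts a `count_tables` from [build_counts()].
#' @param calls_ind the individual's `S x ploidy` call matrix
#'   (see [individual_calls()]).
#' @param from_group,to_group group labels in `1..K`.
#' @return the change in total likelihood ratio (nats).
#' @export
delta_lr_move <- function(counts, calls_ind, from_group, to_group) {
  K <- counts$K
  if (from_group < 1L || from_group > K || to_group < 1L || to_group > K)
    stop("group label out of range 1..K")
  if (from_group == to_group) return(0)
  delta <- 0
  for (tc in move_touch(counts, calls_ind)) {
    tab <- counts$tables[[tc$s]]
    i <- tc$alleles + 1L
    of <- tab[from_group, i]; ot <- tab[to_group, i]
    if (any(of < tc$cnt))
      stop("count table inconsistent with 'from_group' for this individual")
    delta <- delta +
      sum(xlogx(ot + tc$cnt) - xlogx(ot) + xlogx(of - tc$cnt) - xlogx(of))
    rf <- counts$row_totals[from_group, tc$s]
    rt <- counts$row_totals[to_group, tc$s]
    delta <- delta -
      (xlogx(rt + tc$m) - xlogx(rt) + xlogx(rf - tc$m) - xlogx(rf))
  }
  delta
}

#' Apply a single-individual move to count tables
#'
#' Moves one individual's allele calls between group rows, updating the
#' cached marginals; rebuilding from scratch with [build_counts()] after any
#' sequence of moves reproduces the same state exactly.
#'
#' @inheritParams delta_lr_move
#' @return the updated `count_tables`.
#' @export
apply_move <- function(counts, calls_ind, from_group, to_group) {
  K <- counts$K
  if (from_group < 1L || from_group > K || to_group < 1L || to_group > K)
    stop("group label out of range 1..K")
  if (from_group == to_group) return(counts)
  for (tc in move_touch(counts, calls_ind)) {
    i <- tc$alleles + 1L
    if (any(counts$tables[[tc$s]][from_group, i] < tc$cnt))
      stop("count table inconsistent with 'from_group' for this individual")
    counts$tables[[tc$s]][from_group, i] <-
      counts$tables[[tc$s]][from_group, i] - tc$cnt
    counts$tables[[tc$s]][to_group, i] <-
      counts$tables[[tc$s]][to_group, i] + tc$cnt
    counts$row_totals[from_group, tc$s] <-
      counts$row_totals[from_group, tc$s] - tc$m
    counts$row_totals[to_group, tc$s] <-
      counts$row_totals[to_group, tc$s] + tc$m
  }
  counts
}

# per-group allele-1 frequencies and call totals at every biallelic locus
group_freqs <- function(gm, part) {
  counts <- build_counts(gm, part)
  if (any(gm$n_alleles > 2L))
    stop("this objective is defined for biallelic loci only")
  K <- counts$K
  s_all <- length(counts$tables)
  n_calls <- counts$row_totals                    # K x S calls per group
  p <- matrix(NA_real_, K, s_all)
  for (s in seq_len(s_all)) {
    tab <- counts$tables[[s]]
    a1 <- if (ncol(tab) >= 2L) tab[, 2L] else numeric(K)
    p[, s] <- ifelse(n_calls[, s] > 0, a1 / n_calls[, s], NA_real_)
  }
  list(p = p, n = n_calls)
}

#' Summed absolute allele-frequency difference (DAF) between two groups
#'
#' An alternative two-group objective: the sum over biallelic loci of the
#' absolute difference in allele-1 frequency between the two groups. Loci
#' where either group has no non-missing calls contribute 0. Defined only for
#' `K = 2`; it does not extend to more groups, which is one reason the
#' likelihood ratio is the default objective.
#'
#' @param gm a [genotype_matrix()] of biallelic loci.
#' @param part a two-group [partition()].
#' @return the summed absolute frequency difference (unitless, `>= 0`).
#' @export
objective_daf <- function(gm, part) {
  part <- as_partition(part)
  if (n_groups(part) != 2L)
    stop("DAF is defined for K = 2 only; it does not extend to more groups")
  fr <- group_freqs(gm, part)
  d <- abs(fr$p[1L, ] - fr$p[2L, ])
  sum(d[!is.na(d)])
}

#' Multi-locus Hudson-style Fst between groups
#'
#' An alternative objective measuring allele-frequency divergence: the
#' Hudson estimator as a ratio of averages over loci,
#' `sum_s N_s / sum_s D_s` with
#' `N_s = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D_s = p1(1-p2) + p2(1-p1)`, where `p` are group allele-1 frequencies and
#' `n` group call counts. Loci where either group has fewer than two calls are
#' dropped. For `K > 2` the estimate is the average over all group pairs.
#'
#' @param gm a [genotype_matrix()] of biallelic loci.
#' @param part a [partition()] with `K >= 2`.
#' @return the Fst estimate (can be slightly negative under panmixia).
#' @export
objective_fst <- function(gm, part) {
  part <- as_partition(part)
  K <- n_groups(part)
  if (K < 2L) stop("Fst needs at least two groups")
  fr <- group_freqs(gm, part)
  if (any(rowSums(fr$n) == 0))
    stop("a group has zero non-missing calls at every locus")
  pairs <- utils::combn(K, 2L)
  ests <- apply(pairs, 2L, function(pr) {
    p1 <- fr$p[pr[1L], ]; p2 <- fr$p[pr[2L], ]
    n1 <- fr$n[pr[1L], ]; n2 <- fr$n[pr[2L], ]
    ok <- n1 >= 2 & n2 >= 2 & !is.na(p1) & !is.na(p2)
    if (!any(ok)) return(NA_real_)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    if (sum(den[ok]) == 0) return(NA_real_)
    sum(num[ok]) / sum(den[ok])
  })
  mean(ests, na.rm = TRUE)
}
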