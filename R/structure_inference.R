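#' Break population structure by shuffling alleles within loci
#'
#' For each locus independently, randomly permutes the non-missing allele
#' calls across the non-missing call slots of all individuals. Per-locus
#' allele totals and the missingness mask are conserved exactly; any
#' association between alleles and individuals (hence any population
#' structure) is destroyed, which is the null model of [test_structure()].
#'
#' @param gm a [genotype_matrix()].
#' @param seed integer seed.
#' @return a [genotype_matrix()] with identical dimensions, ids, `n_alleles`
#'   and missingness, and per-locus allele counts equal to the input's.
#' @export
permute_alleles <- function(gm, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  calls <- gm$calls
  for (s in seq_len(n_loci(gm))) {
    slot <- calls[, s, ]
    nm <- which(!is.na(slot))
    if (length(nm) > 1L) slot[nm] <- slot[nm][sample.int(length(nm))]
    calls[, s, ] <- slot
  }
  genotype_matrix(calls, gm$individual_ids, gm$locus_ids,
                  n_alleles = gm$n_alleles)
}

#' Permutation test for the existence of population structure
#'
#' A non-homogeneous population can be split into at least two subpopulations,
#' so structure is tested at `K = 2`: the observed data and `n_perm`
#' allele-permuted copies (see [permute_alleles()]) are each clustered into
#' two groups with [anneal()] under the same schedule and restart count, and
#' structure is declared when the observed maximized LR exceeds every null
#' LR. An empirical p-value `(1 + n_at_or_above) / (1 + n_perm)` is
#' reported so other cutoffs can be applied; it counts the null values at or
#' above the observed one.
#'
#' @param gm a [genotype_matrix()].
#' @param n_perm number of allele permutations (default 20).
#' @param schedule a [cooling_schedule()] used for the observed and every
#'   null optimization.
#' @param restarts restarts per optimization.
#' @param seed master seed; permutation and optimization seeds are derived
#'   from it deterministically.
#' @return an object of class `structure_test`: list with `observed_lr`,
#'   `null_lrs`, `structure_detected`, `empirical_p`, `n_perm`,
#'   `observed_partition`.
#' @export
test_structure <- function(gm, n_perm = 20L, schedule = cooling_schedule(),
                           restarts = 10L, seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  seeds <- derive_seeds(seed, 2L * n_perm + 1L)
  obs <- anneal(gm, K = 2L, schedule = schedule, seed = seeds[1L],
                restarts = restarts)
  null_lrs <- vapply(seq_len(n_perm), function(i) {
    pg <- permute_alleles(gm, seed = seeds[2L * i])
    anneal(pg, K = 2L, schedule = schedule, seed = seeds[2L * i + 1L],
           restarts = restarts)$best_lr
  }, numeric(1L))
  res <- list(observed_lr = obs$best_lr, null_lrs = null_lrs,
              structure_detected = obs$best_lr > max(null_lrs),
              empirical_p = (1 + sum(null_lrs >= obs$best_lr)) / (1 + n_perm),
              n_perm = n_perm, observed_partition = obs$best_partition)
  class(res) <- "structure_test"
  res
}

#' @export
print.structure_test <- function(x, ...) {
  cat(sprintf(
    "structure_test (K = 2, %d allele permutations)\n  observed LR = %.3f nats, null LR range = [%.3f, %.3f]\n  structure detected: %s (empirical p = %.3f)\n",
    x$n_perm, x$observed_lr, min(x$null_lrs), max(x$null_lrs),
    x$structure_detected, x$empirical_p))
  invisible(x)
}

#' Best LR as a function of K
#'
#' Runs [anneal()] for every K in `k_min..k_max` (with LR(1) defined as 0 —
#' a single group has expected counts equal to observed counts) and records
#' the best LR per K. Input to [sod_profile()] and [k_max_info()].
#'
#' @param gm a [genotype_matrix()].
#' @param k_min,k_max contiguous K range, `1 <= k_min < k_max <= N`.
#' @param schedule a [cooling_schedule()].
#' @param restarts restarts per K.
#' @param seed master seed; one derived seed per K.
#' @return a data frame of class `lr_profile` with columns `K` and `lr`.
#' @export
lr_profile <- function(gm, k_min = 1L, k_max, schedule = cooling_schedule(),
                       restarts = 10L, seed = 1L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_min >= k_max || k_max > n_individuals(gm))
    stop("need 1 <= k_min < k_max <= number of individuals")
  ks <- k_min:k_max
  seeds <- derive_seeds(seed, length(ks))
  lr <- vapply(seq_along(ks), function(i) {
    if (ks[i] == 1L) return(0)
    anneal(gm, K = ks[i], schedule = schedule, seed = seeds[i],
           restarts = restarts)$best_lr
  }, numeric(1L))
  structure(data.frame(K = ks, lr = lr),
            class = c("lr_profile", "data.frame"))
}

as_lr_profile <- function(x) {
  if (inherits(x, "lr_profile")) return(x)
  if (is.data.frame(x) && all(c("K", "lr") %in% names(x)))
    return(structure(x[c("K", "lr")], class = c("lr_profile", "data.frame")))
  if (is.numeric(x) && !is.null(names(x)))
    return(structure(data.frame(K = as.integer(names(x)), lr = as.numeric(x)),
                     class = c("lr_profile", "data.frame")))
  stop("cannot interpret 'profile'; need columns K and lr")
}

#' Second-order difference of an LR profile
#'
#' `SOD(K) = LR(K) - (LR(K-1) + LR(K+1)) / 2`, the negative half second
#' difference of the LR-versus-K curve, computed for every K whose two
#' neighbours are present in the profile. A large positive SOD marks an
#' elbow: the gain from K-1 to K groups far exceeds the gain from K to K+1.
#'
#' @param profile an `lr_profile` (from [lr_profile()]), a data frame with
#'   columns `K` and `lr`, or a named numeric vector of LR values keyed by K.
#' @return a data frame with columns `K` and `sod`.
#' @export
sod_profile <- function(profile) {
  profile <- as_lr_profile(profile)
  profile <- profile[order(profile$K), ]
  if (nrow(profile) < 3L) stop("profile needs at least three K values")
  if (any(diff(profile$K) != 1L)) stop("profile has gaps in K")
  if (any(!is.finite(profile$lr))) stop("profile has non-finite LR values")
  k <- profile$K
  lr <- profile$lr
  mid <- 2:(length(k) - 1L)
  data.frame(K = k[mid], sod = lr[mid] - (lr[mid - 1L] + lr[mid + 1L]) / 2)
}

#' Maximum informative K
#'
#' Chooses the number of groups from an LR profile over `K = 1..K_max` by a
#' scale-free discriminant on the second-order differences: among candidate
#' `K in 2..(K_max - 3)` satisfying the two guards `SOD(K) > 0` and
#' `SOD(K) > SOD(K+1)` (the elbow must dominate both globally and locally),
#' it returns the K maximizing
#' `SOD(K)^2 / sum(SOD(i)^2, i = K..K_max-1) * (1 - SOD(K+1)/SOD(K))^2`,
#' smallest K on ties. Returns `NA` when no candidate passes the guards
#' (e.g. a linear profile, where every SOD is 0). Multiplying the whole
#' profile by a positive constant leaves the choice unchanged.
#'
#' @param profile as in [sod_profile()]; must cover `K = 1..K_max` with
#'   `K_max >= 6` so the candidate set is non-empty.
#' @return the selected K (integer), or `NA_integer_`; the per-candidate
#'   scores are attached as attribute `discriminant`.
#' @export
k_max_info <- function(profile) {
  profile <- as_lr_profile(profile)
  profile <- profile[order(profile$K), ]
  if (profile$K[1L] != 1L) stop("profile must start at K = 1")
  k_max <- max(profile$K)
  if (k_max < 6L) stop("need K_max >= 6 (candidate set 2..K_max-3 is empty)")
  sod <- sod_profile(profile)            # K = 2 .. k_max - 1
  sodv <- function(k) sod$sod[match(k, sod$K)]
  cand <- 2:(k_max - 3L)
  score <- rep(NA_real_, length(cand))
  for (j in seq_along(cand)) {
    k <- cand[j]
    sk <- sodv(k); sk1 <- sodv(k + 1L)
    if (!(sk > 0) || !(sk > sk1)) next
    norm <- sum(sodv(k:(k_max - 1L))^2)
    if (norm == 0) next
    score[j] <- sk^2 / norm * (1 - sk1 / sk)^2
  }
  if (all(is.na(score)))
    return(structure(NA_integer_,
                     discriminant = stats::setNames(score, cand)))
  structure(cand[which.max(score)],
            discriminant = stats::setNames(score, cand))
}
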