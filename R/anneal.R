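#' Cooling schedule for the partition search
#'
#' Parameters of the simulated-annealing phase followed by zero-temperature
#' (greedy) refinement. Temperatures are geometric: epoch `i` runs at
#' `t0 * alpha^i`. `t0 = "auto"` scales the initial temperature to the data
#' as `max(1, LR(initial assignment) / N)`, so early moves are close to
#' uniform regardless of dataset size.
#'
#' @param t0 initial temperature in nats (the units of the objective), or
#'   `"auto"`.
#' @param alpha geometric cooling factor per epoch, in (0, 1).
#' @param n_epochs number of annealed epochs.
#' @param greedy_epochs maximum number of greedy full passes after annealing;
#'   the greedy phase stops early once a full pass moves nobody.
#' @param steps_per_epoch single-individual updates per epoch; defaults to
#'   the number of individuals, so one epoch is one expected sweep.
#' @return a list of class `cooling_schedule`.
#' @export
cooling_schedule <- function(t0 = "auto", alpha = 0.95, n_epochs = 200L,
                             greedy_epochs = 50L, steps_per_epoch = NULL) {
  if (!identical(t0, "auto")) {
    t0 <- as.numeric(t0)
    if (!is.finite(t0) || t0 <= 0) stop("'t0' must be positive or \"auto\"")
  }
  alpha <- as.numeric(alpha)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  n_epochs <- as.integer(n_epochs)
  greedy_epochs <- as.integer(greedy_epochs)
  if (n_epochs < 1L || greedy_epochs < 1L)
    stop("'n_epochs' and 'greedy_epochs' must be positive")
  if (!is.null(steps_per_epoch)) {
    steps_per_epoch <- as.integer(steps_per_epoch)
    if (steps_per_epoch < 1L) stop("'steps_per_epoch' must be positive")
  }
  structure(list(t0 = t0, alpha = alpha, n_epochs = n_epochs,
                 greedy_epochs = greedy_epochs,
                 steps_per_epoch = steps_per_epoch),
            class = "cooling_schedule")
}

#' One annealed Gibbs update of a single individual's assignment
#'
#' The elementary move of the partition search, exposed for inspection and
#' testing (the fast path inside [anneal()] performs the identical update in
#' compiled code). Individual `r`'s label is redrawn from the Boltzmann
#' distribution over candidate groups, `p(C) proportional to
#' exp(LR(z_r = C) / temperature)`, evaluated stably by subtracting the
#' largest candidate LR, using [delta_lr_move()] so the cost is
#' `O(S * ploidy * K)`. As `temperature -> 0` the move becomes greedy; as
#' `temperature -> Inf` the label is drawn uniformly. Draws use R's RNG
#' stream (seed with [set.seed()]).
#'
#' @param gm a [genotype_matrix()].
#' @param counts the current `count_tables` (consistent with `part`).
#' @param part the current [partition()].
#' @param r index of the individual to update.
#' @param temperature positive temperature in nats.
#' @return list with updated `counts`, `part`, the chosen label `chosen`,
#'   and `delta` (the objective change of the applied move).
#' @export
gibbs_step <- function(gm, counts, part, r, temperature) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be positive")
  part <- as_partition(part)
  K <- n_groups(part)
  g <- unclass(part)[r]
  ci <- individual_calls(gm, r)
  deltas <- vapply(seq_len(K), function(k) delta_lr_move(counts, ci, g, k),
                   numeric(1L))
  if (any(!is.finite(deltas)))
    stop("non-finite LR encountered (count-table corruption)")
  w <- exp((deltas - max(deltas)) / temperature)
  chosen <- sample.int(K, 1L, prob = w)
  if (chosen != g) {
    counts <- apply_move(counts, ci, g, chosen)
    z <- unclass(part)
    z[r] <- chosen
    part <- partition(z, K = K)
  }
  list(counts = counts, part = part, chosen = chosen, delta = deltas[chosen])
}

#' Best K-group assignment by annealed likelihood-ratio maximization
#'
#' Searches for the partition of individuals into `K` groups maximizing the
#' total likelihood ratio ([total_lr()]). Each restart starts from a uniform
#' random assignment and runs annealed Gibbs updates of one randomly chosen
#' individual at a time — the new label is drawn with probability
#' proportional to `exp(LR(candidate) / T)` — followed by greedy
#' hill-climbing passes until no single-individual move improves the
#' objective. The best state ever visited across all restarts is returned.
#'
#' Restart seeds are derived deterministically from `seed`, so results are
#' reproducible and independent of restart execution order. Empty groups are
#' allowed during and after the search; a warning is emitted when fewer than
#' `K` groups are occupied in the result.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of groups (1 returns the trivial partition with LR 0).
#' @param schedule a [cooling_schedule()].
#' @param seed integer master seed for all randomness.
#' @param restarts number of independent restarts.
#' @return an object of class `anneal_result`: list with `best_partition`
#'   (canonical [partition()]), `best_lr` (nats), `lr_trace` (running best LR
#'   per epoch of the winning restart), `n_nonempty_groups`, `restart_index`,
#'   `seed`, `K`.
#' @export
anneal <- function(gm, K, schedule = cooling_schedule(), seed = 1L,
                   restarts = 10L) {
  if (!inherits(gm, "genotype_matrix")) stop("'gm' must be a genotype_matrix")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("'restarts' must be >= 1")
  n <- n_individuals(gm)
  if (K > n) warning("K exceeds the number of individuals")
  if (K == 1L) {
    res <- list(best_partition = partition(rep(1L, n), K = 1L), best_lr = 0,
                lr_trace = rep(0, schedule$n_epochs),
                n_nonempty_groups = 1L, restart_index = 1L, seed = seed, K = 1L)
    class(res) <- "anneal_result"
    return(res)
  }
  calls <- flat_calls(gm)
  steps <- if (is.null(schedule$steps_per_epoch)) n else schedule$steps_per_epoch
  rs <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(rs[r])
    z0 <- sample.int(K, n, replace = TRUE)
    t0 <- schedule$t0
    if (identical(t0, "auto")) {
      lr0 <- total_lr_core(calls, gm$n_alleles, z0, K)
      t0 <- max(1, lr0 / n)
    }
    out <- anneal_core(calls, gm$n_alleles, K, z0, t0, schedule$alpha,
                       schedule$n_epochs, schedule$greedy_epochs, steps,
                       as.numeric(rs[r]))
    if (!is.finite(out$best_lr))
      stop("non-finite LR encountered (count-table corruption)")
    if (is.null(best) || out$best_lr > best$best_lr + 1e-12) {
      best <- out
      best$restart_index <- r
    }
  }
  part <- canonicalize_partition(partition(best$z, K = K))
  occupied <- length(unique(unclass(part)))
  if (occupied < K)
    warning(sprintf("only %d of K = %d groups are occupied", occupied, K))
  res <- list(best_partition = part, best_lr = best$best_lr,
              lr_trace = cummax(best$trace),
              n_nonempty_groups = occupied,
              restart_index = best$restart_index, seed = seed, K = K)
  class(res) <- "anneal_result"
  res
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf(
    "anneal_result: K = %d (%d occupied), best LR = %.4f nats (restart %d, seed %d)\n",
    x$K, x$n_nonempty_groups, x$best_lr, x$restart_index, x$seed))
  print(table(group = unclass(x$best_partition)))
  invisible(x)
}

# one master seed -> a reproducible vector of sub-seeds (31-bit), used for
# restarts, permutation replicates and profile entries so each unit of work
# has its own stream and results do not depend on execution order
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
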