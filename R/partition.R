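#' Partition of individuals into K groups
#'
#' @param z integer vector of group labels in `1..K`, one per individual.
#' @param K number of groups; defaults to `max(z)`. Empty groups (labels in
#'   `1..K` that never occur) are allowed.
#' @return an integer vector of class `partition` with attribute `K`.
#' @export
partition <- function(z, K = max(z)) {
  z <- as.integer(z)
  K <- as.integer(K)
  if (length(z) < 1L) stop("empty partition")
  if (K < 1L) stop("K must be >= 1")
  if (anyNA(z) || any(z < 1L | z > K))
    stop("group labels must be integers in 1..K")
  structure(z, K = K, class = "partition")
}

as_partition <- function(x, K = NULL) {
  if (inherits(x, "partition") && is.null(K)) return(x)
  partition(unclass(x), K = if (is.null(K)) max(as.integer(x)) else K)
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition of %d individuals into K = %d groups (%d non-empty)\n",
              length(x), n_groups(x), length(unique(unclass(x)))))
  print(table(group = unclass(x)))
  invisible(x)
}

#' Number of groups of a partition
#' @param part a [partition()].
#' @return the (declared) number of groups `K`.
#' @export
n_groups <- function(part) attr(part, "K")

#' Canonical relabeling of a partition
#'
#' Relabels groups by order of first appearance, the canonical form used to
#' compare partitions across runs (group labels are arbitrary: any relabeling
#' leaves the likelihood-ratio objective unchanged). Idempotent.
#'
#' @param part a [partition()] or integer label vector.
#' @return a [partition()] in canonical form with the same `K`.
#' @export
canonicalize_partition <- function(part) {
  part <- as_partition(part)
  z <- unclass(part)
  first <- unique(z)
  partition(match(z, first), K = n_groups(part))
}
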