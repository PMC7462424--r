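#' Allegiance (agreement) matrix from a set of partitions
#'
#' Entry (i, j) is the fraction of the supplied partitions in which
#' regions i and j share a community. From a subject's Louvain iterations
#' this is the subject-level allegiance; from the cohort's subject
#' partitions it is the group-level allegiance.
#'
#' @param partitions non-empty list of equal-length label vectors.
#' @return symmetric numeric matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
allegiance_from_partitions <- function(partitions) {
  if (length(partitions) == 0) stop("need at least one partition")
  n <- length(partitions[[1]])
  if (any(vapply(partitions, length, integer(1)) != n)) {
    stop("all partitions must have the same length")
  }
  acc <- matrix(0, n, n)
  for (p in partitions) acc <- acc + outer(p, p, "==")
  acc / length(partitions)
}

#' Consensus partition of an allegiance matrix
#'
#' Iterative consensus clustering: threshold the allegiance matrix at
#' `tau` (entries below `tau` set to 0, diagonal removed), partition the
#' thresholded agreement matrix `reps` times with [louvain_partition()],
#' rebuild the agreement matrix from those partitions, and repeat until
#' all `reps` partitions coincide. Disconnected components of the
#' thresholded matrix may become separate communities. Resolution for the
#' agreement-matrix re-clustering defaults to 1 regardless of the gamma
#' used on the raw networks.
#'
#' @param a allegiance matrix (square, symmetric, entries in \[0, 1\]).
#' @param tau agreement threshold in \[0, 1).
#' @param reps number of Louvain repartitions per iteration.
#' @param gamma resolution for re-clustering the agreement matrix.
#' @param seed optional integer seed.
#' @param max_iter iteration cap; non-convergence raises an error carrying
#'   the last agreement matrix (`condition$agreement`).
#' @return integer community label vector (canonical).
#' @export
consensus_partition <- function(a, tau = 0.5, reps = 100, gamma = 1,
                                seed = NULL, max_iter = 50) {
  a <- as.matrix(a)
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)")
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  for (iter in seq_len(max_iter)) {
    at <- a
    at[at < tau] <- 0
    diag(at) <- 0
    net <- weighted_network(at)
    parts <- lapply(seq_len(reps), function(r) {
      louvain_partition(net, gamma = gamma)$partition
    })
    if (.all_identical_partitions(parts)) {
      return(parts[[1]])
    }
    a <- allegiance_from_partitions(parts)
  }
  stop(errorCondition(
    paste0("consensus clustering did not converge in ", max_iter,
           " iterations"),
    agreement = a,
    class = c("betanet_consensus_error", "error")
  ))
}

.all_identical_partitions <- function(parts) {
  first <- canonical_partition(parts[[1]])
  for (p in parts[-1]) {
    if (!identical(canonical_partition(p), first)) return(FALSE)
  }
  TRUE
}

#' Subject-level consensus partition and allegiance
#'
#' Runs `n_iter` Louvain partitions of a subject's network at resolution
#' `gamma`, builds the subject-level allegiance matrix, and clusters it
#' into a consensus partition at threshold `tau`.
#'
#' @param net a `weighted_network`.
#' @param gamma structural resolution parameter.
#' @param n_iter number of Louvain iterations (1000 at final analysis
#'   scale; smaller values are appropriate during sweeps).
#' @param tau consensus threshold.
#' @param seed optional integer seed.
#' @param consensus_reps Louvain repartitions per consensus iteration.
#' @return list with `partition` and `allegiance`.
#' @export
subject_consensus <- function(net, gamma = 1, n_iter = 1000, tau = 0.5,
                              seed = NULL, consensus_reps = 100) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(seq_len(n_iter), function(i) {
    louvain_partition(net, gamma = gamma)$partition
  })
  a <- allegiance_from_partitions(parts)
  partition <- if (n_iter == 1) {
    parts[[1]]
  } else {
    consensus_partition(a, tau = tau, reps = consensus_reps)
  }
  list(partition = partition, allegiance = a)
}

#' Group-level consensus partition and allegiance
#'
#' Builds the across-subject allegiance matrix (fraction of subjects in
#' which two regions share a community) from final subject-level
#' partitions and clusters it with the same consensus procedure.
#'
#' @param subject_partitions list of subject-level label vectors.
#' @param tau consensus threshold (the same threshold is applied at the
#'   subject and group levels).
#' @param gamma resolution for the agreement-matrix re-clustering.
#' @param seed optional integer seed.
#' @param consensus_reps Louvain repartitions per consensus iteration.
#' @return list with `partition` and `allegiance`.
#' @export
group_consensus <- function(subject_partitions, tau = 0.5, gamma = 1,
                            seed = NULL, consensus_reps = 100) {
  if (!is.null(seed)) set.seed(seed)
  a <- allegiance_from_partitions(subject_partitions)
  partition <- if (length(subject_partitions) == 1) {
    canonical_partition(subject_partitions[[1]])
  } else {
    consensus_partition(a, tau = tau, reps = consensus_reps, gamma = gamma)
  }
  list(partition = partition, allegiance = a)
}
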