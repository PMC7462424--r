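#' Community set of a group partition
#'
#' @param partition group-level community label vector.
#' @return object of class `community_set`: list with `communities` (named
#'   list, label -> region indices), `sizes` and `singleton` flags.
#' @export
community_set <- function(partition) {
  partition <- canonical_partition(partition)
  comms <- split(seq_along(partition), partition)
  sizes <- vapply(comms, length, integer(1))
  structure(
    list(communities = comms, sizes = sizes, singleton = sizes == 1,
         partition = partition),
    class = "community_set"
  )
}

#' @export
print.community_set <- function(x, ...) {
  cat("Community set:", length(x$communities), "communities (",
      sum(!x$singleton), "nonsingleton,", sum(x$singleton), "singleton)\n")
  invisible(x)
}

#' Select communities with reliable subject-level modularity contribution
#'
#' For each community of the group partition, the observed statistic is
#' the mean over subjects of its contribution Q_c* to the subject-level
#' networks. The null distribution is built from size-matched uniformly
#' random region sets (resampled without replacement, pooled across
#' subjects by the same mean), and a community is selected when its
#' observed statistic exceeds the `percentile`-th percentile of its null.
#'
#' @param subject_nets list of `weighted_network` for one condition.
#' @param group_part group-level partition for that condition.
#' @param gamma structural resolution parameter used for Q_c*.
#' @param n_null number of null draws (must be >= 1).
#' @param percentile selection percentile in (50, 100).
#' @param seed optional integer seed.
#' @return data.frame, one row per community: `community`, `size`,
#'   `observed`, `null_cutoff`, `selected`.
#' @export
select_communities <- function(subject_nets, group_part, gamma = 1,
                               n_null = 1000, percentile = 99,
                               seed = NULL) {
  if (n_null < 1) stop("n_null must be >= 1")
  if (percentile <= 50 || percentile >= 100) {
    stop("percentile must be in (50, 100)")
  }
  if (!is.null(seed)) set.seed(seed)
  cs <- community_set(group_part)
  n <- length(cs$partition)
  Bs <- lapply(subject_nets, modularity_matrix, gamma = gamma)

  mean_qc <- function(idx) {
    mean(vapply(Bs, function(B) sum(B[idx, idx]), numeric(1)))
  }
  out <- data.frame(community = as.integer(names(cs$communities)),
                    size = unname(cs$sizes),
                    observed = NA_real_, null_cutoff = NA_real_,
                    selected = NA)
  for (k in seq_along(cs$communities)) {
    idx <- cs$communities[[k]]
    obs <- mean_qc(idx)
    nulls <- vapply(seq_len(n_null), function(i) {
      mean_qc(sample.int(n, length(idx)))
    }, numeric(1))
    cutoff <- unname(quantile(nulls, percentile / 100, type = 7))
    out$observed[k] <- obs
    out$null_cutoff[k] <- cutoff
    out$selected[k] <- obs > cutoff
  }
  out
}

# paired-t statistic on a difference matrix D (pairs x draws); columns
# with zero variance give NA
.paired_t_cols <- function(D) {
  k <- nrow(D)
  if (k == 1) return(as.numeric(D))
  m <- colMeans(D)
  s <- sqrt(pmax(colSums(D^2) - k * m^2, 0) / (k - 1))
  ifelse(s == 0, NA_real_, m / (s / sqrt(k)))
}

#' Monte Carlo test of community allegiance differences between conditions
#'
#' For every community pair (self-pairs included), the vector of
#' below-diagonal region-pair allegiance values (within-community pairs,
#' or all cross-community pairs) is extracted from the two condition-wise
#' group allegiance matrices and compared with a paired t statistic
#' (`T_true`); a community with exactly one region pair uses the simple
#' difference. The null relabels each subject's condition assignment with
#' probability 1/2 per iteration, rebuilds both group allegiance matrices
#' and recomputes every statistic; `z = (T_true - mean(T_null)) /
#' sd(T_null)` and two-tailed `p = (#{|T_null| >= |T_true|} + 1) /
#' (n_perm + 1)`. An identically zero difference vector returns z = 0,
#' p = 1 with a warning. Benjamini-Hochberg flags are appended over all
#' `k (k + 1) / 2` tests.
#'
#' @param aA,aB condition-wise group allegiance matrices built from the
#'   same subjects.
#' @param communities a `community_set` (or label vector) defining the
#'   communities to test.
#' @param parts_A,parts_B lists of subject-level partitions per condition
#'   (same subject order).
#' @param n_perm number of Monte Carlo iterations (>= 100; the analysis
#'   scale is 50,000).
#' @param seed optional integer seed.
#' @param fdr_q Benjamini-Hochberg level.
#' @return data.frame with one row per community pair: `community_a`,
#'   `community_b`, `n_pairs`, `t`, `z`, `p`, `fdr_significant`; attribute
#'   `n_tests`.
#' @export
community_allegiance_difference <- function(aA, aB, communities,
                                            parts_A, parts_B,
                                            n_perm = 1000, seed = NULL,
                                            fdr_q = 0.05) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (length(parts_A) != length(parts_B)) {
    stop("both conditions need the same subjects")
  }
  if (!inherits(communities, "community_set")) {
    communities <- community_set(communities)
  }
  if (!is.null(seed)) set.seed(seed)
  n_subj <- length(parts_A)
  coA <- lapply(parts_A, function(p) outer(p, p, "==") * 1)
  coB <- lapply(parts_B, function(p) outer(p, p, "==") * 1)

  comms <- communities$communities
  k <- length(comms)
  pairs <- cbind(rep(seq_len(k), times = seq_len(k)),
                 unlist(lapply(seq_len(k), seq_len)))
  colnames(pairs) <- c("b", "a")
  # swap signs: +1 keeps the subject's labels, -1 exchanges them
  E <- matrix(sample(c(1, -1), n_subj * n_perm, replace = TRUE),
              n_subj, n_perm)

  res <- data.frame(community_a = integer(0), community_b = integer(0),
                    n_pairs = integer(0), t = numeric(0), z = numeric(0),
                    p = numeric(0))
  degenerate <- FALSE
  for (r in seq_len(nrow(pairs))) {
    ca <- pairs[r, "a"]
    cb <- pairs[r, "b"]
    ia <- comms[[ca]]
    ib <- comms[[cb]]
    if (ca == cb) {
      if (length(ia) < 2) next  # singleton: no region pair to test
      grid_idx <- which(lower.tri(matrix(0, length(ia), length(ia))),
                        arr.ind = TRUE)
      rows <- ia[grid_idx[, 1]]
      cols <- ia[grid_idx[, 2]]
    } else {
      grid_idx <- expand.grid(i = ia, j = ib)
      rows <- grid_idx$i
      cols <- grid_idx$j
    }
    flat <- cbind(rows, cols)
    vA <- vapply(coA, function(m) m[flat], numeric(nrow(flat)))
    vB <- vapply(coB, function(m) m[flat], numeric(nrow(flat)))
    vA <- matrix(vA, nrow = nrow(flat))
    vB <- matrix(vB, nrow = nrow(flat))
    D <- vA - vB  # pairs x subjects
    d_true <- cbind(aA[flat] - aB[flat])
    t_true <- .paired_t_cols(d_true)
    if (is.na(t_true)) {  # zero-variance difference vector
      degenerate <- TRUE
      res <- rbind(res, data.frame(community_a = ca, community_b = cb,
                                   n_pairs = nrow(flat), t = 0, z = 0,
                                   p = 1))
      next
    }
    Dnull <- (D %*% E) / n_subj  # pairs x n_perm mean differences
    t_null <- .paired_t_cols(Dnull)
    t_null[is.na(t_null)] <- 0
    mu <- mean(t_null)
    sig <- sd(t_null)
    z <- if (sig == 0) 0 else (t_true - mu) / sig
    p <- (sum(abs(t_null) >= abs(t_true)) + 1) / (n_perm + 1)
    res <- rbind(res, data.frame(community_a = ca, community_b = cb,
                                 n_pairs = nrow(flat), t = t_true, z = z,
                                 p = p))
  }
  if (degenerate) {
    warning("zero-variance allegiance difference for some community pair(s); z = 0, p = 1 reported")
  }
  res$fdr_significant <- bh_fdr(res$p, q = fdr_q)
  attr(res, "n_tests") <- nrow(res)
  res
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `q` (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvals p values in \[0, 1\].
#' @param q FDR level.
#' @return logical vector of significance flags.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p values must be in [0, 1]")
  }
  p.adjust(pvals, method = "BH") <= q
}
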