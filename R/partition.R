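#' Canonicalize community labels
#'
#' Renumbers labels to consecutive integers ordered by first appearance,
#' so structurally identical partitions compare equal with `identical()`.
#'
#' @param labels integer (or coercible) community label vector.
#' @return integer vector of canonical labels starting at 1.
#' @export
canonical_partition <- function(labels) {
  if (length(labels) == 0) stop("empty partition")
  match(labels, unique(labels))
}

#' Optimally match community labels between two partitions
#'
#' Relabels `target` so that total overlap with `reference` is maximized
#' (optimal assignment on the contingency table, solved exactly by the
#' Hungarian algorithm). Membership structure is unchanged; target
#' communities with no matched reference community receive fresh labels
#' beyond the reference's largest label.
#'
#' @param reference,target integer community label vectors of equal length.
#' @return integer label vector: `target` relabeled into `reference`'s
#'   label space.
#' @export
match_labels <- function(reference, target) {
  if (length(reference) != length(target)) {
    stop("partitions must have equal length")
  }
  reference <- as.integer(canonical_partition(reference))
  target <- as.integer(canonical_partition(target))
  kr <- max(reference)
  kt <- max(target)
  k <- max(kr, kt)
  overlap <- matrix(0, k, k)
  tab <- table(factor(target, levels = seq_len(k)),
               factor(reference, levels = seq_len(k)))
  overlap[seq_len(k), seq_len(k)] <- as.matrix(tab)
  assign <- hungarian_min(-overlap)  # rows = target communities
  newlab <- integer(kt)
  fresh <- kr
  for (ct in seq_len(kt)) {
    cr <- assign[ct]
    if (cr <= kr && overlap[ct, cr] > 0) {
      newlab[ct] <- cr
    } else {
      fresh <- fresh + 1L
      newlab[ct] <- fresh
    }
  }
  newlab[target]
}

#' Normalized variation of information between two partitions
#'
#' `VI = H(p1) + H(p2) - 2 MI(p1, p2)`, normalized by `log(n)`. The
#' logarithm base cancels in the normalized quantity (natural log used).
#' By convention the distance is 0 for single-node partitions.
#'
#' @param p1,p2 community label vectors of equal length.
#' @return normalized VI in \[0, 1\].
#' @export
normalized_vi <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions must have equal length")
  n <- length(p1)
  if (n == 1) return(0)
  joint <- table(p1, p2) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  vi <- ent(px) + ent(py) - 2 * mi
  max(0, vi / log(n))
}

#' Region flexibility between two task conditions
#'
#' After optimal label matching, flags each region that changes its
#' community assignment between the two condition-wise partitions. With
#' two conditions flexibility is binary: 1 = changed, 0 = stable.
#'
#' @param pA,pB condition-wise community label vectors.
#' @return integer 0/1 vector, one element per region.
#' @export
flexibility_between_conditions <- function(pA, pB) {
  pA <- canonical_partition(pA)
  matched <- match_labels(pA, pB)
  as.integer(matched != pA)
}
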