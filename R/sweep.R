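#' Arithmetic grid of structural resolution values
#'
#' Default grid spans gamma = 0.05 to 5.0 in steps of 0.05 (100 values),
#' the range over which community structure typically evolves from a
#' single module to all-singleton partitions for z-scored functional
#' networks.
#'
#' @param start,stop,step grid limits and spacing.
#' @return numeric vector of gamma values with attribute `step`.
#' @export
gamma_grid <- function(start = 0.05, stop = 5.0, step = 0.05) {
  if (step <= 0 || stop < start) stop("invalid gamma grid")
  values <- seq(start, stop, by = step)
  attr(values, "step") <- step
  values
}

#' Per-subject maximum modularity across the resolution sweep
#'
#' For each subject, condition and gamma, extracts the maximum Q* observed
#' over `n_iter` Louvain iterations, then compares conditions with a
#' paired t test at every gamma (p values are reported uncorrected).
#' Identical condition-wise values give a difference of exactly 0 and
#' p = 1.
#'
#' @param nets_A,nets_B lists of `weighted_network`, one per subject, in
#'   matching subject order.
#' @param grid gamma grid (see [gamma_grid()]).
#' @param n_iter Louvain iterations per subject/condition/gamma.
#' @param seed optional integer seed.
#' @return list with `qmax` (array subjects x gammas x conditions) and
#'   `tests` (data.frame: gamma, mean_diff, t, p).
#' @export
global_modularity_curve <- function(nets_A, nets_B, grid, n_iter = 100,
                                    seed = NULL) {
  if (length(nets_A) != length(nets_B)) {
    stop("both conditions must be present for every subject")
  }
  if (!is.null(seed)) set.seed(seed)
  n_subj <- length(nets_A)
  qmax <- array(NA_real_, dim = c(n_subj, length(grid), 2),
                dimnames = list(NULL, NULL, c("A", "B")))
  for (s in seq_len(n_subj)) {
    BA <- nets_A[[s]]
    BB <- nets_B[[s]]
    for (g in seq_along(grid)) {
      qa <- vapply(seq_len(n_iter), function(i) {
        louvain_partition(BA, gamma = grid[g])$qstar
      }, numeric(1))
      qb <- vapply(seq_len(n_iter), function(i) {
        louvain_partition(BB, gamma = grid[g])$qstar
      }, numeric(1))
      qmax[s, g, "A"] <- max(qa)
      qmax[s, g, "B"] <- max(qb)
    }
  }
  tests <- data.frame(gamma = as.numeric(grid), mean_diff = NA_real_,
                      t = NA_real_, p = NA_real_)
  for (g in seq_along(grid)) {
    d <- qmax[, g, "A"] - qmax[, g, "B"]
    tests$mean_diff[g] <- mean(d)
    if (length(d) < 2 || sd(d) == 0) {
      tests$t[g] <- 0
      tests$p[g] <- 1
    } else {
      tt <- t.test(qmax[, g, "A"], qmax[, g, "B"], paired = TRUE)
      tests$t[g] <- unname(tt$statistic)
      tests$p[g] <- tt$p.value
    }
  }
  list(qmax = qmax, tests = tests)
}

#' Run the group consensus pipeline across a resolution sweep
#'
#' At every gamma and repeat, partitions each subject's condition-wise
#' network (`n_iter_subject` Louvain iterations + subject consensus) and
#' derives the group consensus partition per condition. Records the
#' condition-wise group partitions, the SD of the between-condition
#' flexibility vector per repeat (repeats paired by index), and optionally
#' the subject-level partitions of the first repeat (used by the
#' region-level analysis).
#'
#' @param cohort list per subject of lists with `weighted_network`
#'   elements `A` and `B` (as returned by
#'   [generate_connectivity_cohort()]).
#' @param grid gamma grid.
#' @param n_repeats group-pipeline repeats per gamma.
#' @param n_iter_subject Louvain iterations per subject during the sweep.
#' @param tau consensus threshold.
#' @param seed optional integer seed.
#' @param consensus_reps Louvain repartitions per consensus iteration.
#' @param keep_subject_partitions store repeat-1 subject partitions.
#' @return object of class `sweep_result`: list with `grid`, `n_repeats`,
#'   `group_partitions` (list \[gamma\]\[\[repeat\]\] with elements `A`,
#'   `B`), `flex_sd` (matrix gammas x repeats), and optionally
#'   `subject_partitions` (list \[gamma\] with `A`, `B` lists of subject
#'   label vectors).
#' @export
run_gamma_sweep <- function(cohort, grid, n_repeats = 100,
                            n_iter_subject = 100, tau = 0.5, seed = NULL,
                            consensus_reps = 50,
                            keep_subject_partitions = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n_gamma <- length(grid)
  group_partitions <- vector("list", n_gamma)
  subject_partitions <- if (keep_subject_partitions) {
    vector("list", n_gamma)
  }
  flex_sd <- matrix(NA_real_, n_gamma, n_repeats)
  for (g in seq_len(n_gamma)) {
    reps <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      parts <- list(A = vector("list", length(cohort)),
                    B = vector("list", length(cohort)))
      for (s in seq_along(cohort)) {
        for (cond in c("A", "B")) {
          parts[[cond]][[s]] <- subject_consensus(
            cohort[[s]][[cond]], gamma = grid[g], n_iter = n_iter_subject,
            tau = tau, consensus_reps = consensus_reps)$partition
        }
      }
      gA <- group_consensus(parts$A, tau = tau,
                            consensus_reps = consensus_reps)$partition
      gB <- group_consensus(parts$B, tau = tau,
                            consensus_reps = consensus_reps)$partition
      reps[[r]] <- list(A = gA, B = gB)
      flex_sd[g, r] <- sd(flexibility_between_conditions(gA, gB))
      if (keep_subject_partitions && r == 1) {
        subject_partitions[[g]] <- parts
      }
    }
    group_partitions[[g]] <- reps
  }
  structure(
    list(grid = grid, n_repeats = n_repeats,
         group_partitions = group_partitions, flex_sd = flex_sd,
         subject_partitions = subject_partitions),
    class = "sweep_result"
  )
}

#' Partition stability across the sweep (normalized VI in a window)
#'
#' At each gamma, the mean pairwise normalized variation of information
#' among the group partitions at grid points within `window_gamma / 2` of
#' that gamma (per condition and repeat), averaged over repeats and
#' conditions. Low values indicate that no new community organization is
#' being discovered as gamma changes.
#'
#' @param sweep a `sweep_result`.
#' @param window_gamma window width in gamma units; must span at least two
#'   grid steps (default 0.35, i.e. +-3 steps on the default grid).
#' @return data.frame with columns `gamma` and `mean_nvi`.
#' @export
vi_stability_curve <- function(sweep, window_gamma = 0.35) {
  stopifnot(inherits(sweep, "sweep_result"))
  grid <- sweep$grid
  step <- attr(grid, "step")
  if (is.null(step)) step <- if (length(grid) > 1) diff(grid)[1] else NA
  half <- floor((window_gamma / 2) / step)
  if (is.na(half) || half < 1) {
    stop("window_gamma must span at least two grid steps")
  }
  n_gamma <- length(grid)
  out <- data.frame(gamma = as.numeric(grid), mean_nvi = NA_real_)
  for (g in seq_len(n_gamma)) {
    win <- max(1, g - half):min(n_gamma, g + half)
    vals <- c()
    for (r in seq_len(sweep$n_repeats)) {
      for (cond in c("A", "B")) {
        ps <- lapply(win, function(gg) sweep$group_partitions[[gg]][[r]][[cond]])
        if (length(ps) >= 2) {
          prs <- utils::combn(length(ps), 2)
          vals <- c(vals, apply(prs, 2, function(ij) {
            normalized_vi(ps[[ij[1]]], ps[[ij[2]]])
          }))
        }
      }
    }
    out$mean_nvi[g] <- mean(vals)
  }
  out
}

#' Select the working resolution by flexibility variability
#'
#' The working gamma maximizes the mean (over index-paired repeats)
#' standard deviation across regions of the between-condition flexibility
#' vector — the point where stable and changing community assignments are
#' best balanced (the SD of a binary vector is maximal when exactly half
#' the regions change). Ties break toward smaller gamma; an identically
#' zero curve (conditions identical at every gamma) returns the smallest
#' grid value with a warning.
#'
#' @param sweep a `sweep_result` computed with at least 2 repeats (a
#'   single repeat is accepted with the single SD per gamma).
#' @return list with `gamma_star` and `curve` (data.frame gamma,
#'   mean_flex_sd).
#' @export
select_gamma <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  mean_sd <- rowMeans(sweep$flex_sd)
  curve <- data.frame(gamma = as.numeric(sweep$grid), mean_flex_sd = mean_sd)
  if (all(mean_sd == 0)) {
    warning("flexibility SD is zero at every gamma; returning the smallest grid value")
    return(list(gamma_star = as.numeric(sweep$grid[1]), curve = curve))
  }
  list(gamma_star = as.numeric(sweep$grid[which.max(mean_sd)]), curve = curve)
}
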