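#' Specify a planted community model for synthetic cohorts
#'
#' Describes the generative ground truth used by [generate_cohort()] and
#' [generate_connectivity_cohort()]: two condition-wise partitions of the
#' regions (largely shared, with a designated set of regions changing
#' membership), target trial-level correlations within and between
#' communities, noise scales, a per-volume censoring rate, and the cohort
#' size. `changed_regions` is derived, not supplied: it is the set of
#' regions whose label differs between the two partitions after optimal
#' label matching.
#'
#' @param partition_A,partition_B integer community label vectors, one per
#'   region, for conditions A and B.
#' @param rho_within,rho_between target trial-level correlations for region
#'   pairs inside / across ground-truth communities; `0 <= rho_between <
#'   rho_within <= 1`.
#' @param sigma_noise volume-level (or, for the direct connectivity
#'   sampler, edge-level) Gaussian noise scale.
#' @param effect_scale_by_community optional list with elements `A` and/or
#'   `B`, each a named numeric vector mapping community labels (of the
#'   matching condition's partition) to multipliers on `rho_within`; used
#'   to plant condition-specific allegiance differences.
#' @param censor_rate per-volume probability of censoring, in \[0, 1).
#' @param n_subjects cohort size.
#' @param seed integer seed stored with the model; generators draw all
#'   randomness from it.
#' @return an object of class `planted_model`.
#' @export
planted_model <- function(partition_A,
                          partition_B = partition_A,
                          rho_within = 0.6,
                          rho_between = 0.1,
                          sigma_noise = 1,
                          effect_scale_by_community = NULL,
                          censor_rate = 0,
                          n_subjects = 20,
                          seed = 1) {
  partition_A <- canonical_partition(partition_A)
  partition_B <- canonical_partition(partition_B)
  if (length(partition_A) != length(partition_B)) {
    stop("partition_A and partition_B must have the same length")
  }
  if (!(rho_between >= 0 && rho_between < rho_within && rho_within <= 1)) {
    stop("require 0 <= rho_between < rho_within <= 1")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must be in [0, 1)")
  }
  matched_B <- match_labels(partition_A, partition_B)
  changed <- which(matched_B != partition_A)
  structure(
    list(n_regions = length(partition_A),
         partition_A = partition_A,
         partition_B = matched_B,
         changed_regions = changed,
         rho_within = rho_within,
         rho_between = rho_between,
         sigma_noise = sigma_noise,
         effect_scale_by_community = effect_scale_by_community,
         censor_rate = censor_rate,
         n_subjects = n_subjects,
         seed = as.integer(seed)),
    class = "planted_model"
  )
}

#' @export
print.planted_model <- function(x, ...) {
  cat("Planted model:", x$n_regions, "regions,",
      max(x$partition_A), "/", max(x$partition_B), "communities (A/B),",
      length(x$changed_regions), "changed regions,",
      x$n_subjects, "subjects\n")
  cat("  rho_within =", x$rho_within, ", rho_between =", x$rho_between,
      ", sigma_noise =", x$sigma_noise, ", censor_rate =", x$censor_rate, "\n")
  invisible(x)
}

# per-region within-community correlation targets for one condition,
# after applying any per-community effect scaling (capped just below 1)
.rho_within_by_region <- function(model, condition) {
  part <- if (condition == "A") model$partition_A else model$partition_B
  rho <- rep(model$rho_within, model$n_regions)
  scales <- model$effect_scale_by_community[[condition]]
  if (!is.null(scales)) {
    for (lab in names(scales)) {
      idx <- part == as.integer(lab)
      rho[idx] <- min(model$rho_within * scales[[lab]], 0.99)
    }
  }
  if (any(rho < model$rho_between)) {
    stop("effect scaling pushed a within-community correlation below rho_between")
  }
  rho
}
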