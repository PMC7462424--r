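#' Simulate a synthetic subject cohort with planted community structure
#'
#' For every subject and trial, one latent amplitude is drawn per
#' ground-truth community (using the partition of the trial's condition) on
#' top of a global factor, and each region's trial amplitude is
#' `sqrt(rho_b) * global + sqrt(rho_w - rho_b) * community + sqrt(1 - rho_w)
#' * noise`, so that the expected trial-level correlation is `rho_within`
#' inside communities and `rho_between` across them. Amplitudes are
#' convolved with the double-gamma HRF on the TR grid, volume-level
#' Gaussian noise of scale `sigma_noise` is added, and a per-volume keep
#' mask is drawn i.i.d. with censoring probability `censor_rate`.
#' Ground-truth betas (the drawn amplitudes) are recorded per subject.
#'
#' @param design a `trial_design` from [generate_task_design()].
#' @param model a `planted_model`.
#' @param hrf haemodynamic kernel function of time in seconds.
#' @return an object of class `synthetic_cohort`: list with `subjects`
#'   (each with `roi_timeseries` (volumes x regions), `censor_mask`
#'   (1 = keep), `ground_truth_betas` (trials x regions)), `design`,
#'   and `model`.
#' @export
generate_cohort <- function(design, model, hrf = hrf_double_gamma) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "planted_model"))
  set.seed(model$seed)
  trials <- design$trials
  n_trials <- nrow(trials)
  n_reg <- model$n_regions
  n_vol <- design$n_volumes

  # per-trial regressors shared with the LS-S estimator
  R <- .trial_regressors(design, hrf)
  rho_b <- model$rho_between
  rho_w_A <- .rho_within_by_region(model, "A")
  rho_w_B <- .rho_within_by_region(model, "B")

  subjects <- vector("list", model$n_subjects)
  for (s in seq_len(model$n_subjects)) {
    amp <- matrix(0, n_trials, n_reg)
    for (t in seq_len(n_trials)) {
      cond <- trials$condition[t]
      part <- if (cond == "A") model$partition_A else model$partition_B
      rho_w <- if (cond == "A") rho_w_A else rho_w_B
      g0 <- rnorm(1)
      gc <- rnorm(max(part))
      amp[t, ] <- sqrt(rho_b) * g0 +
        sqrt(rho_w - rho_b) * gc[part] +
        sqrt(1 - rho_w) * rnorm(n_reg)
    }
    y <- R %*% amp + model$sigma_noise * matrix(rnorm(n_vol * n_reg), n_vol, n_reg)
    keep <- as.integer(runif(n_vol) >= model$censor_rate)
    subjects[[s]] <- list(roi_timeseries = y,
                          censor_mask = keep,
                          ground_truth_betas = amp)
  }
  structure(list(subjects = subjects, design = design, model = model),
            class = "synthetic_cohort")
}

# volumes x trials matrix of HRF-convolved single-trial regressors,
# evaluated at volume acquisition times (0, tr, 2 tr, ...). The kernel is
# truncated at the design's single-trial response span, so the volumes a
# trial's regressor touches are exactly those counted by the scrubbing
# rule, and trials separated by more than the span do not overlap.
.trial_regressors <- function(design, hrf = hrf_double_gamma) {
  tv <- (seq_len(design$n_volumes) - 1) * design$tr
  onsets <- design$trials$onset_s
  vapply(onsets, function(o) {
    dt <- tv - o
    hrf(dt) * (dt <= design$response_dur)
  }, numeric(design$n_volumes))
}

#' Directly sample subject connectivity matrices from a planted model
#'
#' Fast path that bypasses time series and beta estimation: each subject's
#' condition-wise network is a noisy realization of the block matrix
#' implied by the planted partition, with entries on the Fisher-Z scale
#' (`atanh(rho)`, scaled by `sqrt(n_obs - 3)` to mimic z-scored
#' connectivity), symmetric Gaussian noise of scale `sigma_noise`, and a
#' zero diagonal.
#'
#' @param model a `planted_model`.
#' @param n_obs nominal number of retained betas behind each matrix (sets
#'   the z-score scale).
#' @return list (length `n_subjects`) of lists with elements `A` and `B`,
#'   each a `weighted_network`.
#' @export
generate_connectivity_cohort <- function(model, n_obs = 80) {
  stopifnot(inherits(model, "planted_model"))
  set.seed(model$seed)
  n <- model$n_regions
  scale <- sqrt(n_obs - 3)

  block_z <- function(part, rho_w_region) {
    same <- outer(part, part, "==")
    # within-community rho for a pair: the (common) per-region target
    rho <- matrix(model$rho_between, n, n)
    rho[same] <- outer(rho_w_region, rho_w_region, pmin)[same]
    z <- atanh(rho) * scale
    diag(z) <- 0
    z
  }
  mA <- block_z(model$partition_A, .rho_within_by_region(model, "A"))
  mB <- block_z(model$partition_B, .rho_within_by_region(model, "B"))

  noisy <- function(m) {
    e <- matrix(0, n, n)
    ut <- upper.tri(m)
    e[ut] <- rnorm(sum(ut), sd = model$sigma_noise)
    e <- e + t(e)
    w <- m + e
    diag(w) <- 0
    weighted_network(w, n_obs = n_obs)
  }
  lapply(seq_len(model$n_subjects), function(s) {
    list(A = noisy(mA), B = noisy(mB))
  })
}
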