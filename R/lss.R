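#' Build the least-squares-separate (LS-S) design matrix for one trial
#'
#' Columns are: the HRF-convolved stick regressor for the trial of
#' interest; a single HRF-convolved regressor combining all other trials;
#' any per-volume nuisance covariates; and an intercept. One row per
#' volume. Censoring is applied later by row deletion in the per-trial fit.
#'
#' @param design a `trial_design`.
#' @param trial_index which trial (1-based) is the trial of interest.
#' @param hrf haemodynamic kernel function.
#' @param nuisance optional matrix of per-volume covariates (n_volumes
#'   rows); an all-zero block is dropped.
#' @return numeric matrix (n_volumes x p) with named columns.
#' @export
build_lss_design <- function(design, trial_index, hrf = hrf_double_gamma,
                             nuisance = NULL) {
  stopifnot(inherits(design, "trial_design"))
  n_trials <- nrow(design$trials)
  if (trial_index < 1 || trial_index > n_trials) {
    stop("trial_index out of range")
  }
  R <- .trial_regressors(design, hrf)
  X <- cbind(trial = R[, trial_index])
  if (n_trials > 1) {
    X <- cbind(X, others = rowSums(R[, -trial_index, drop = FALSE]))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != design$n_volumes) {
      stop("nuisance must have one row per volume")
    }
    nz <- apply(nuisance, 2, function(col) any(col != 0))
    if (any(nz)) {
      nui <- nuisance[, nz, drop = FALSE]
      colnames(nui) <- paste0("nuisance", seq_len(ncol(nui)))
      X <- cbind(X, nui)
    }
  }
  cbind(X, intercept = 1)
}

#' Estimate a trial-level beta series with the LS-S method
#'
#' Fits one ordinary-least-squares GLM per trial (a regressor for the
#' trial of interest plus one combining all other trials, nuisance
#' covariates and an intercept), after deleting censored volumes, and
#' keeps the trial-of-interest coefficient for every region. Trials whose
#' design is rank deficient after censor-row deletion get missing betas
#' (and are treated as scrubbed downstream).
#'
#' @param timeseries numeric matrix, volumes x regions.
#' @param design a `trial_design`.
#' @param censor optional keep mask (1 = keep) of length n_volumes;
#'   `NULL` keeps all volumes.
#' @param hrf haemodynamic kernel function.
#' @param nuisance optional per-volume covariate matrix.
#' @return a `beta_series` object (see [beta_series()]), split by
#'   condition, with non-finite trials marked as not retained.
#' @export
estimate_beta_series <- function(timeseries, design, censor = NULL,
                                 hrf = hrf_double_gamma, nuisance = NULL) {
  stopifnot(inherits(design, "trial_design"))
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) != design$n_volumes) {
    stop("timeseries must have n_volumes rows")
  }
  if (is.null(censor)) censor <- rep(1L, design$n_volumes)
  if (length(censor) != design$n_volumes) {
    stop("censor mask length must equal n_volumes")
  }
  keep <- censor != 0
  n_trials <- nrow(design$trials)
  n_reg <- ncol(timeseries)
  betas <- matrix(NA_real_, n_reg, n_trials)
  Yk <- timeseries[keep, , drop = FALSE]
  for (t in seq_len(n_trials)) {
    X <- build_lss_design(design, t, hrf = hrf, nuisance = nuisance)
    Xk <- X[keep, , drop = FALSE]
    qx <- qr(Xk)
    if (qx$rank < ncol(Xk)) next  # rank deficient: beta stays missing
    cf <- qr.coef(qx, Yk)
    betas[, t] <- cf[1L, ]
  }
  beta_series(betas, design)
}
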