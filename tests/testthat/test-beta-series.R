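# small separated design: trials further apart than the response span,
# so each trial's regressor has disjoint support
separated_design <- function(n_per = 4, seed = 2) {
  generate_task_design(n_trials_per_condition = n_per, numerosities = 2,
                       isi_set = 15000, seed = seed)
}

test_that("LS-S design matrix has the documented column structure", {
  d <- generate_task_design(n_trials_per_condition = 1, numerosities = 2,
                            isi_set = 4000, seed = 1)
  X <- build_lss_design(d, 1)
  expect_equal(colnames(X), c("trial", "others", "intercept"))
  expect_equal(nrow(X), d$n_volumes)
  nui <- matrix(rnorm(d$n_volumes * 2), ncol = 2)
  X2 <- build_lss_design(d, 1, nuisance = nui)
  expect_equal(ncol(X2), 5)
  # an all-zero nuisance block is dropped and leaves betas unchanged
  X3 <- build_lss_design(d, 1, nuisance = matrix(0, d$n_volumes, 3))
  expect_equal(X3, X)
  expect_error(build_lss_design(d, 5), "out of range")
})

test_that("noise-free betas are recovered exactly when the GLM spans the signal", {
  # 2 trials: the LS-S model (trial + other + intercept) spans the data
  d <- generate_task_design(n_trials_per_condition = 1, numerosities = 2,
                            isi_set = 4000, seed = 1)
  pm <- planted_model(rep(1:2, each = 3), rho_within = 0.8,
                      rho_between = 0.1, sigma_noise = 0,
                      n_subjects = 1, seed = 2)
  co <- generate_cohort(d, pm)
  s <- co$subjects[[1]]
  bs <- estimate_beta_series(s$roi_timeseries, d)
  est <- cbind(bs$betas$A, bs$betas$B)[, order(unlist(bs$trial_index))]
  expect_equal(est, t(s$ground_truth_betas), tolerance = 1e-6)
})

test_that("LS-S betas on separated noise-free trials are near ground truth", {
  # with more than two trials the combined-others regressor is an
  # approximation; with disjoint supports the residual coupling is only
  # through the intercept and stays small
  d <- separated_design(6)
  pm <- planted_model(rep(1:2, each = 4), rho_within = 0.8,
                      rho_between = 0.1, sigma_noise = 0,
                      n_subjects = 1, seed = 3)
  co <- generate_cohort(d, pm)
  s <- co$subjects[[1]]
  bs <- estimate_beta_series(s$roi_timeseries, d)
  est <- cbind(bs$betas$A, bs$betas$B)[, order(unlist(bs$trial_index))]
  expect_lt(max(abs(est - t(s$ground_truth_betas))), 0.02)
})

test_that("beta estimates are unbiased over a noisy cohort", {
  d <- separated_design(4)
  pm <- planted_model(rep(1:2, each = 5), rho_within = 0.6,
                      rho_between = 0.1, sigma_noise = 1,
                      n_subjects = 40, seed = 9)
  co <- generate_cohort(d, pm)
  errs <- vapply(co$subjects, function(s) {
    bs <- estimate_beta_series(s$roi_timeseries, d)
    est <- cbind(bs$betas$A, bs$betas$B)[, order(unlist(bs$trial_index))]
    mean(est - t(s$ground_truth_betas))
  }, numeric(1))
  ci <- t.test(errs)$conf.int
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("a fully censored trial yields a missing, scrubbed beta", {
  d <- separated_design(2)
  pm <- planted_model(rep(1:2, each = 3), sigma_noise = 0,
                      n_subjects = 1, seed = 4)
  co <- generate_cohort(d, pm)
  s <- co$subjects[[1]]
  censor <- rep(1L, d$n_volumes)
  span <- trial_response_span(d$trials$onset_s[1], d$tr, d$n_volumes,
                              d$response_dur)
  censor[span] <- 0L
  bs <- estimate_beta_series(s$roi_timeseries, d, censor = censor)
  cond1 <- d$trials$condition[1]
  k <- which(bs$trial_index[[cond1]] == 1)
  expect_true(all(is.na(bs$betas[[cond1]][, k])))
  expect_false(bs$retained[[cond1]][k])
  # other trials unaffected
  expect_true(all(is.finite(unlist(bs$betas)[!is.na(unlist(bs$betas))])))
})

test_that("scrubbing removes trials with two or more censored volumes", {
  d <- separated_design(3)
  pm <- planted_model(rep(1:2, each = 3), sigma_noise = 0,
                      n_subjects = 1, seed = 5)
  co <- generate_cohort(d, pm)
  bs0 <- estimate_beta_series(co$subjects[[1]]$roi_timeseries, d)

  spans <- lapply(d$trials$onset_s, trial_response_span, tr = d$tr,
                  n_volumes = d$n_volumes, response_dur = d$response_dur)
  censor <- rep(1L, d$n_volumes)
  censor[spans[[1]][c(2, 4)]] <- 0L  # trial 1: two censored volumes
  censor[spans[[2]][3]] <- 0L        # trial 2: exactly one
  bs <- scrub_trials(bs0, d, censor)
  cond <- d$trials$condition
  expect_false(bs$retained[[cond[1]]][bs$trial_index[[cond[1]]] == 1])
  expect_true(bs$retained[[cond[2]]][bs$trial_index[[cond[2]]] == 2])

  # all-ones mask retains everything; scrubbing is monotone
  bs_id <- scrub_trials(bs0, d, rep(1L, d$n_volumes))
  expect_equal(bs_id$retained, bs0$retained)
  censor2 <- censor
  censor2[spans[[3]][c(1, 2)]] <- 0L
  bs2 <- scrub_trials(bs0, d, censor2)
  expect_true(all(bs2$n_retained <= bs$n_retained))
})

test_that("within-condition normalization matches the stated convention", {
  d <- generate_task_design(n_trials_per_condition = 3, numerosities = 2,
                            isi_set = 5000, seed = 6)
  cond <- d$trials$condition
  betas <- matrix(0, 1, 6)
  betas[1, cond == "A"] <- c(1, 2, 3)
  betas[1, cond == "B"] <- c(4, 5, 9)
  bs <- beta_series(betas, d)
  bn <- normalize_within_condition(bs)
  expect_equal(as.numeric(bn$betas$A), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  bn2 <- normalize_within_condition(bs, sd_type = "sample")
  expect_equal(as.numeric(bn2$betas$A), c(-1, 0, 1), tolerance = 1e-12)
  # per-region mean 0, SD 1; idempotent
  expect_lt(abs(mean(bn$betas$B)), 1e-12)
  expect_equal(sqrt(mean((bn$betas$B - mean(bn$betas$B))^2)), 1,
               tolerance = 1e-12)
  expect_equal(normalize_within_condition(bn)$betas, bn$betas,
               tolerance = 1e-12)
  # zero-SD region is a named error
  betas0 <- rbind(betas, 1)
  expect_error(normalize_within_condition(beta_series(betas0, d)),
               "region\\(s\\) 2")
})

test_that("Fisher-z connectivity matches the closed form", {
  d <- generate_task_design(n_trials_per_condition = 30, numerosities = 2,
                            isi_set = 5000, seed = 7)
  set.seed(1)
  betas <- matrix(rnorm(4 * 60), 4, 60)
  idxA <- which(d$trials$condition == "A")
  betas[1:2, idxA] <- betas_with_exact_r(0.5, 30)  # exact r = 0.5, N = 30
  net <- compute_connectivity(beta_series(betas, d), "A")
  expect_equal(net$n_obs, 30)
  expect_equal(net$w[1, 2], atanh(0.5) * sqrt(27), tolerance = 1e-10)
  expect_equal(net$w[1, 2], 2.8541, tolerance = 1e-4)
  expect_equal(net$w, t(net$w))
  expect_equal(diag(net$w), rep(0, 4))
  # zero correlation maps to z = 0
  betas0 <- betas
  betas0[3:4, idxA] <- betas_with_exact_r(0, 30)
  net0 <- compute_connectivity(beta_series(betas0, d), "A")
  expect_equal(net0$w[3, 4], 0, tolerance = 1e-12)
})

test_that("connectivity is invariant to affine rescaling and clamps r = 1", {
  d <- generate_task_design(n_trials_per_condition = 5, numerosities = 2,
                            isi_set = 5000, seed = 8)
  set.seed(2)
  betas <- matrix(rnorm(3 * 10), 3, 10)
  bs <- beta_series(betas, d)
  net1 <- compute_connectivity(bs, "A")
  betas2 <- betas * c(2, -0.5, 10) + c(1, -3, 7)
  net2 <- compute_connectivity(beta_series(betas2, d), "A")
  expect_equal(abs(net2$w), abs(net1$w), tolerance = 1e-10)
  # perfectly shared signal: clamped z at the ceiling, with a warning
  betas3 <- rbind(betas[1, ], betas[1, ], betas[1, ])
  expect_warning(net3 <- compute_connectivity(beta_series(betas3, d), "A"),
                 "clamped")
  expect_equal(net3$w[1, 2], atanh(1 - 1e-12) * sqrt(5 - 3))
  expect_error(compute_connectivity(bs, "C"), "unknown condition")
})
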