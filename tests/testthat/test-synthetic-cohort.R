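test_that("planted model derives changed_regions from the partitions", {
  pA <- rep(1:3, each = 4)
  pB <- pA
  pB[c(1, 5)] <- c(2L, 3L)
  pm <- planted_model(pA, pB, n_subjects = 1)
  expect_equal(pm$changed_regions, c(1L, 5L))
  # label permutation of the same structure: no changed regions
  pm0 <- planted_model(pA, c(3L, 1L, 2L)[pA], n_subjects = 1)
  expect_length(pm0$changed_regions, 0)
  expect_error(planted_model(pA, rho_within = 0.2, rho_between = 0.5),
               "rho_between")
  expect_error(planted_model(pA, censor_rate = 1), "censor_rate")
})

test_that("cohorts are bit-identical given the same seed", {
  d <- generate_task_design(n_trials_per_condition = 6,
                            numerosities = c(2, 4), seed = 5)
  pm <- planted_model(rep(1:2, each = 4), n_subjects = 2, seed = 11)
  c1 <- generate_cohort(d, pm)
  c2 <- generate_cohort(d, pm)
  expect_identical(c1, c2)
})

test_that("ground-truth beta correlations converge to the planted targets", {
  d <- generate_task_design(n_trials_per_condition = 150, numerosities = 2,
                            isi_set = c(3300, 5300, 7300), seed = 2)
  pm <- planted_model(rep(1:3, each = 5), rho_within = 0.8,
                      rho_between = 0.1, n_subjects = 1, seed = 4)
  co <- generate_cohort(d, pm)
  amp <- co$subjects[[1]]$ground_truth_betas
  idxA <- which(d$trials$condition == "A")
  r <- cor(amp[idxA, ])
  same <- outer(pm$partition_A, pm$partition_A, "==")
  diag(same) <- NA
  expect_lt(abs(mean(r[same & !is.na(same)]) - 0.8), 0.1)
  expect_lt(abs(mean(r[!same & !is.na(same)]) - 0.1), 0.1)
})

test_that("censoring rate matches its binomial sampling distribution", {
  d <- generate_task_design(seed = 3)  # default-size run
  pm <- planted_model(rep(1:2, each = 3), censor_rate = 0.05,
                      n_subjects = 4, seed = 6)
  co <- generate_cohort(d, pm)
  keep <- unlist(lapply(co$subjects, `[[`, "censor_mask"))
  n <- length(keep)
  frac <- mean(keep == 0)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("noise-free connectivity cohorts have exact recoverable blocks", {
  pm <- planted_model(rep(1:3, each = 6), rho_within = 0.6,
                      rho_between = 0.1, sigma_noise = 0,
                      n_subjects = 2, seed = 7)
  nets <- generate_connectivity_cohort(pm)
  w <- nets[[1]]$A$w
  same <- outer(pm$partition_A, pm$partition_A, "==")
  diag(same) <- NA
  expect_true(all(w[which(same)] == w[which(same)][1]))
  expect_true(all(w[which(!same)] == w[which(!same)][1]))
  lv <- louvain_partition(nets[[1]]$A, gamma = 1, seed = 1)
  expect_equal(normalized_vi(lv$partition, pm$partition_A), 0)
})

test_that("connectivity cohorts plant condition-specific allegiance effects", {
  pm <- planted_model(rep(1:3, each = 6), rho_within = 0.5,
                      rho_between = 0.1, sigma_noise = 0,
                      effect_scale_by_community = list(A = c("1" = 1.5)),
                      n_subjects = 1, seed = 8)
  nets <- generate_connectivity_cohort(pm)
  c1 <- which(pm$partition_A == 1)
  c2 <- which(pm$partition_A == 2)
  within1_A <- nets[[1]]$A$w[c1[1], c1[2]]
  within1_B <- nets[[1]]$B$w[c1[1], c1[2]]
  within2_A <- nets[[1]]$A$w[c2[1], c2[2]]
  expect_gt(within1_A, within1_B)
  expect_equal(within2_A, within1_B)
})
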