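# subject partitions with independent label noise around a base partition
simulate_subject_partitions <- function(base, n_subjects, q = 0.15) {
  lapply(seq_len(n_subjects), function(s) noisy_partition(base, q))
}

test_that("community sets partition the regions", {
  p <- c(1L, 1L, 2L, 3L, 3L, 3L)
  cs <- community_set(p)
  expect_equal(sort(unname(unlist(cs$communities))), 1:6)
  expect_equal(unname(cs$sizes), c(2L, 1L, 3L))
  expect_equal(unname(cs$singleton), c(FALSE, TRUE, FALSE))
})

test_that("planted communities are selected; random sets are not", {
  part <- rep(1:3, each = 6)
  pm <- planted_model(part, rho_within = 0.6, rho_between = 0.05,
                      sigma_noise = 1, n_subjects = 8, seed = 61)
  nets <- lapply(generate_connectivity_cohort(pm), `[[`, "A")
  sel <- select_communities(nets, part, gamma = 1, n_null = 300,
                            percentile = 99, seed = 1)
  expect_true(all(sel$selected))
  # a partition of size-matched random sets should rarely be selected
  set.seed(2)
  rand_part <- sample(part)
  sel_r <- select_communities(nets, rand_part, gamma = 1, n_null = 300,
                              percentile = 99, seed = 3)
  expect_lte(sum(sel_r$selected), 1)
  expect_error(select_communities(nets, part, n_null = 0), "n_null")
  expect_error(select_communities(nets, part, percentile = 40),
               "percentile")
})

test_that("identical allegiance matrices give z = 0, p = 1 everywhere", {
  base <- rep(1:3, each = 4)
  set.seed(3)
  parts <- simulate_subject_partitions(base, 8)
  a <- allegiance_from_partitions(parts)
  expect_warning(
    res <- community_allegiance_difference(a, a, base, parts, parts,
                                           n_perm = 200, seed = 4),
    "zero-variance"
  )
  expect_true(all(res$z == 0))
  expect_true(all(res$p == 1))
})

test_that("within/between pair vectors partition the below-diagonal entries", {
  base <- c(rep(1L, 4), rep(2L, 3), rep(3L, 2), 4L)
  set.seed(5)
  partsA <- simulate_subject_partitions(base, 6)
  partsB <- simulate_subject_partitions(base, 6)
  aA <- allegiance_from_partitions(partsA)
  aB <- allegiance_from_partitions(partsB)
  res <- community_allegiance_difference(aA, aB, base, partsA, partsB,
                                         n_perm = 200, seed = 6)
  n <- length(base)
  expect_equal(sum(res$n_pairs), n * (n - 1) / 2)
  # k = 4 communities, one singleton: 4*5/2 pairs minus the singleton self-pair
  expect_equal(nrow(res), 4 * 5 / 2 - 1)
  expect_true(all(res$p >= 1 / 201 & res$p <= 1))
  expect_error(
    community_allegiance_difference(aA, aB, base, partsA, partsB,
                                    n_perm = 10),
    "n_perm"
  )
})

test_that("a planted within-community allegiance increase is detected", {
  base <- rep(1:3, each = 5)
  set.seed(7)
  partsB <- simulate_subject_partitions(base, 14, q = 0.35)
  # condition A: community 1 regions always together (strong allegiance)
  partsA <- lapply(seq_len(14), function(s) {
    p <- noisy_partition(base, 0.35)
    p[base == 1] <- 1L
    p
  })
  aA <- allegiance_from_partitions(partsA)
  aB <- allegiance_from_partitions(partsB)
  res <- community_allegiance_difference(aA, aB, base, partsA, partsB,
                                         n_perm = 500, seed = 8)
  row1 <- res[res$community_a == 1 & res$community_b == 1, ]
  expect_gt(row1$z, qnorm(0.975))
  expect_lt(row1$p, 0.05)
})

test_that("BH flags match the step-up hand computation", {
  # step-up by hand: sorted p_(k) <= k q / m holds up to k = 2
  # (0.01 <= 0.0125, 0.02 <= 0.025, but 0.04 > 0.0375)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.9), q = 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(0.001, 8), q = 0.05), rep(TRUE, 8))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # 10 communities (all nonsingleton) produce 55 within+between tests
  base10 <- rep(1:10, each = 2)
  set.seed(9)
  pa <- simulate_subject_partitions(base10, 5, q = 0.1)
  pb <- simulate_subject_partitions(base10, 5, q = 0.1)
  res <- community_allegiance_difference(allegiance_from_partitions(pa),
                                         allegiance_from_partitions(pb),
                                         base10, pa, pb, n_perm = 100,
                                         seed = 10)
  expect_equal(attr(res, "n_tests"), 55)
})
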