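test_that("profile dissimilarity matches Fisher-Z hand computations", {
  # build 4-region matrices whose region-1 profiles have exact r = 0.5
  x <- c(-1, 0, 1) / sqrt(2)
  e <- c(1, -2, 1) / sqrt(6)
  y <- 0.5 * x + sqrt(0.75) * e
  aA <- diag(4); aB <- diag(4)
  aA[1, 2:4] <- x; aA[2:4, 1] <- x
  aB[1, 2:4] <- y; aB[2:4, 1] <- y
  expect_equal(profile_dissimilarity(aA, aB, region = 1), -atanh(0.5),
               tolerance = 1e-12)
  expect_equal(-atanh(0.5), -0.5493, tolerance = 1e-4)
  # identical matrices: clamped, maximally negative (most similar)
  set.seed(1)
  p <- lapply(1:4, function(i) sample(1:2, 6, replace = TRUE))
  a <- allegiance_from_partitions(p)
  d_same <- profile_dissimilarity(a, a)
  expect_true(all(d_same == -atanh(1 - 1e-12), na.rm = TRUE))
  # orthogonal profiles give exactly 0
  aB2 <- aB
  aB2[1, 2:4] <- e; aB2[2:4, 1] <- e  # e is orthogonal to x, mean 0
  expect_equal(profile_dissimilarity(aA, aB2, region = 1), 0,
               tolerance = 1e-12)
  # constant profile is undefined
  aC <- matrix(1, 4, 4)
  expect_true(is.na(profile_dissimilarity(aC, aB, region = 1)))
})

test_that("region sweep is calibrated under the null and recovers planted changes", {
  base <- rep(1:4, each = 8)
  n_gamma <- 12
  grid <- gamma_grid(0.5, 0.5 + 0.1 * (n_gamma - 1), 0.1)
  set.seed(2)
  null_parts <- function() {
    lapply(seq_len(n_gamma), function(g) {
      lapply(1:10, function(s) noisy_partition(base, 0.2))
    })
  }
  rs0 <- region_sweep(null_parts(), null_parts(), grid, n_perm = 150,
                      alpha = 0.05, seed = 3)
  # marginal counts approximately Binomial(n_gamma, alpha)
  expect_lt(abs(mean(rs0$counts) - 0.05 * n_gamma), 1.0)
  expect_true(all(rs0$counts <= n_gamma))

  # planted change: regions 1:4 move to another community in condition B
  baseB <- base
  baseB[1:4] <- 2L
  set.seed(4)
  pa <- lapply(seq_len(n_gamma), function(g) {
    lapply(1:10, function(s) noisy_partition(base, 0.1))
  })
  pb <- lapply(seq_len(n_gamma), function(g) {
    lapply(1:10, function(s) noisy_partition(baseB, 0.1))
  })
  rs1 <- region_sweep(pa, pb, grid, n_perm = 150, alpha = 0.05, seed = 5)
  top4 <- order(rs1$counts, decreasing = TRUE)[1:4]
  expect_setequal(top4, 1:4)
})

test_that("negative-binomial fitting recovers parameters and falls back", {
  set.seed(6)
  f <- fit_negative_binomial(rnbinom(2000, size = 2, mu = 5))
  expect_equal(f$type, "nbinom")
  expect_lt(abs(f$size - 2), 0.5)
  expect_lt(abs(f$mu - 5), 0.3)
  # Poisson data: dispersion at the boundary for most draws
  set.seed(7)
  f_pois <- fit_negative_binomial(rpois(500, 3))
  expect_true(f_pois$type %in% c("poisson", "nbinom"))
  # truly underdispersed counts always take the fallback
  f_under <- fit_negative_binomial(rep(c(3L, 4L), 50))
  expect_equal(f_under$type, "poisson")
  expect_equal(fit_negative_binomial(rep(5L, 20))$type, "poisson")
  expect_warning(f0 <- fit_negative_binomial(rep(0L, 20)), "degenerate")
  expect_equal(f0$type, "degenerate")
  expect_error(fit_negative_binomial(c(1, 2)), "at least 10")
  expect_error(fit_negative_binomial(c(rep(1, 10), 2.5)), "integers")
})

test_that("p_obs is monotone and extreme counts are flagged", {
  set.seed(8)
  counts <- rnbinom(100, size = 2, mu = 3)
  counts[1] <- 60L  # single extreme region
  fit <- fit_negative_binomial(counts)
  out <- detect_outlier_regions(counts, fit)
  expect_true(out$flagged[1])
  expect_lt(out$p_obs[1], 1e-4)
  # monotone: p_obs non-increasing in the count
  ord <- order(out$count)
  expect_true(all(diff(out$p_obs[ord]) <= 1e-12))
  # QQ residuals of model-consistent data are centred near zero
  set.seed(9)
  counts2 <- rnbinom(200, size = 2, mu = 3)
  fit2 <- fit_negative_binomial(counts2)
  out2 <- detect_outlier_regions(counts2, fit2)
  expect_lt(mean(abs(out2$qq_residual)), 1.5)
})
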