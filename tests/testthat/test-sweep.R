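make_small_cohort <- function(n_subjects = 4, sigma = 1, seed = 55,
                              changed = 0) {
  part <- rep(1:3, each = 6)
  pB <- part
  if (changed > 0) {
    idx <- seq_len(changed)
    pB[idx] <- (part[idx] %% 3) + 1L
  }
  pm <- planted_model(part, pB, rho_within = 0.6, rho_between = 0.1,
                      sigma_noise = sigma, n_subjects = n_subjects,
                      seed = seed)
  list(model = pm, nets = generate_connectivity_cohort(pm))
}

test_that("gamma grid construction follows the arithmetic contract", {
  g <- gamma_grid()
  expect_length(g, 100)
  expect_equal(g[1], 0.05)
  expect_equal(g[100], 5.0)
  expect_equal(unique(round(diff(g), 10)), 0.05)
  expect_error(gamma_grid(1, 0.5, 0.1), "invalid")
})

test_that("identical condition matrices give zero differences and p = 1", {
  co <- make_small_cohort(3)
  nets <- lapply(co$nets, function(x) list(A = x$A, B = x$A))
  grid <- gamma_grid(0.5, 1.5, 0.5)
  res <- global_modularity_curve(lapply(nets, `[[`, "A"),
                                 lapply(nets, `[[`, "B"),
                                 grid, n_iter = 10, seed = 1)
  expect_equal(res$tests$mean_diff, rep(0, 3))
  expect_equal(res$tests$p, rep(1, 3))
})

test_that("at gamma = 0 the max Q* equals the one-community value", {
  part <- rep(1:2, each = 5)
  net <- block_network(part, z_within = 4, z_between = 1)  # nonnegative
  res <- global_modularity_curve(list(net), list(net), c(0), n_iter = 20,
                                 seed = 2)
  expect_equal(unname(res$qmax[1, 1, "A"]),
               modularity_qstar(net, rep(1, 10), gamma = 0),
               tolerance = 1e-12)
})

test_that("VI stability curve is zero for constant partitions and checks its window", {
  co <- make_small_cohort(3, sigma = 0.5)
  grid <- gamma_grid(0.8, 1.6, 0.2)
  sw <- run_gamma_sweep(co$nets, grid, n_repeats = 2, n_iter_subject = 15,
                        seed = 3, consensus_reps = 20)
  expect_s3_class(sw, "sweep_result")
  # well-separated model: partitions constant over this gamma range
  curve <- vi_stability_curve(sw, window_gamma = 0.5)
  expect_equal(curve$mean_nvi, rep(0, length(grid)))
  expect_error(vi_stability_curve(sw, window_gamma = 0.2), "two grid steps")
})

test_that("gamma selection peaks where planted changes are expressed", {
  co <- make_small_cohort(4, sigma = 0.5, changed = 6)
  grid <- gamma_grid(0.6, 2.2, 0.4)
  sw <- run_gamma_sweep(co$nets, grid, n_repeats = 2, n_iter_subject = 15,
                        seed = 4, consensus_reps = 20)
  sel <- select_gamma(sw)
  expect_true(sel$gamma_star %in% grid)
  expect_gt(max(sel$curve$mean_flex_sd), 0)
  expect_equal(sel$curve$mean_flex_sd[sel$curve$gamma == sel$gamma_star],
               max(sel$curve$mean_flex_sd))
})

test_that("gamma selection warns and returns the smallest value when degenerate", {
  co <- make_small_cohort(3, sigma = 0.5)
  nets <- lapply(co$nets, function(x) list(A = x$A, B = x$A))
  grid <- gamma_grid(0.8, 1.2, 0.4)
  sw <- run_gamma_sweep(nets, grid, n_repeats = 2, n_iter_subject = 10,
                        seed = 5, consensus_reps = 20)
  expect_warning(sel <- select_gamma(sw), "zero at every gamma")
  expect_equal(sel$gamma_star, grid[1])
})
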