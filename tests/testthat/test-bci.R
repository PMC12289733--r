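test_that("closed-form likelihoods match numeric integration", {
  p <- bci_p()
  expect_equal(bci_likelihood_common(0, 0, p), 1 / (2 * pi * sqrt(3)),
               tolerance = 1e-10)
  expect_equal(bci_likelihood_common(0, 0, p), oracle_lik_common(0, 0, p),
               tolerance = 1e-8)
  expect_equal(bci_likelihood_independent(0, 0, p), 1 / (4 * pi),
               tolerance = 1e-10)
  expect_equal(bci_likelihood_independent(0, 0, p),
               oracle_lik_independent(0, 0, p), tolerance = 1e-8)

  # asymmetric parameter point
  p2 <- bci_p(sigma_a = 4, sigma_v = 1.5, sigma_p = 10, mu_p = 3)
  expect_equal(bci_likelihood_common(7, -2, p2),
               oracle_lik_common(7, -2, p2), tolerance = 1e-8)
  expect_equal(bci_likelihood_independent(7, -2, p2),
               oracle_lik_independent(7, -2, p2), tolerance = 1e-8)
})

test_that("likelihood structure: monotone in disparity, symmetric", {
  p <- bci_p()
  deltas <- c(0, 1, 2, 5, 10)
  vals <- vapply(deltas, function(d)
    bci_likelihood_common(d / 2, -d / 2, p), numeric(1))
  expect_true(all(diff(vals) < 0))
  # swapping (x_v, sigma_v) with (x_a, sigma_a) leaves the value unchanged
  p_sw <- bci_p(sigma_a = 2, sigma_v = 5)
  expect_equal(bci_likelihood_common(3, -1, bci_p(sigma_a = 5, sigma_v = 2)),
               bci_likelihood_common(-1, 3, p_sw), tolerance = 1e-12)
})

test_that("posterior respects the prior limits and the oracle", {
  p1 <- bci_p(p_common = 1); p0 <- bci_p(p_common = 0)
  for (x in list(c(0, 0), c(10, -3))) {
    expect_equal(bci_posterior_common(x[1], x[2], p1), 1)
    expect_equal(bci_posterior_common(x[1], x[2], p0), 0)
  }
  expect_equal(bci_posterior_common(0, 0, bci_p()), 0.5358984,
               tolerance = 1e-6)
  expect_equal(bci_posterior_common(0, 0, bci_p()),
               oracle_posterior(0, 0, bci_p()), tolerance = 1e-8)

  # strictly increasing in p_common; non-increasing in |disparity|
  pcs <- seq(0.1, 0.9, by = 0.2)
  post <- vapply(pcs, function(pc)
    bci_posterior_common(3, -3, bci_p(p_common = pc)), numeric(1))
  expect_true(all(diff(post) > 0))
  deltas <- c(0, 2, 4, 8, 16)
  post_d <- vapply(deltas, function(d)
    bci_posterior_common(d / 2, -d / 2, bci_p(sigma_p = 10)), numeric(1))
  expect_true(all(diff(post_d) <= 0))
})

test_that("conditional estimates are precision-weighted means", {
  p <- bci_p()
  est <- bci_conditional_estimates(12, 0, p)
  expect_equal(est$s_c1, 4)
  expect_equal(est$s_c1, oracle_c1_mean(12, 0, p), tolerance = 1e-8)
  # all inputs equal c: estimates pinned at c
  estc <- bci_conditional_estimates(7, 7, bci_p(mu_p = 7))
  expect_equal(unlist(estc), c(s_c1 = 7, s_a_c2 = 7, s_v_c2 = 7))
  # flat prior limit reduces the fused estimate to MLE fusion
  p_flat <- bci_p(sigma_a = 2, sigma_v = 1, sigma_p = 1e6)
  expect_equal(bci_conditional_estimates(10, 0, p_flat)$s_c1,
               mle_estimate(0, 10, 2, 1)$estimate, tolerance = 1e-6)
})

test_that("model averaging combines the conditional estimates", {
  r <- run_model("bci", av_stim(45, 39),
                 list(p_common = 0.5, sigma_a = 5, sigma_v = 5,
                      sigma_p = 5, mu_p = 45))
  post <- r$causes
  est <- r$metadata$conditionals
  expect_equal(r$metadata$estimates$auditory,
               post * est$s_c1 + (1 - post) * est$s_a_c2, tolerance = 1e-12)
  # spec-level oracle for the causes value at this stimulus pair
  p <- bci_p(sigma_a = 5, sigma_v = 5, sigma_p = 5, mu_p = 45,
             p_common = 0.5)
  expect_equal(post, oracle_posterior(39, 45, p), tolerance = 1e-8)

  # forced fusion at p_common = 1
  r1 <- run_model("bci", av_stim(45, 39),
                  list(p_common = 1, sigma_a = 5, sigma_v = 5,
                       sigma_p = 5, mu_p = 45))
  expect_equal(r1$causes, 1)
  expect_equal(r1$metadata$estimates$auditory,
               r1$metadata$conditionals$s_c1, tolerance = 1e-12)
})

test_that("the temporal dimension reuses the same machinery in ms", {
  st <- list(stimulus("auditory", 90, onset = 240, duration = 100),
             stimulus("visual", 90, onset = 160, duration = 100))
  r <- run_model("bci", st, list(p_common = 0.6, sigma_a = 40,
                                 sigma_v = 40, sigma_p = 60),
                 dimension = "time")
  expect_equal(r$metadata$measurements$x_a, 240)
  expect_equal(r$metadata$resolved$mu_p, 160)  # visual-onset prior
  expect_true(r$causes > 0 && r$causes < 1)
})

test_that("the unity curve over temporal disparities is unimodal", {
  tab <- run_task("bci", default_task("explicit_temporal"),
                  params = list(p_common = 0.5, sigma_a = 50, sigma_v = 50,
                                sigma_p = 60))
  expect_identical(nrow(tab), 8L)
  u <- tab$unity[order(abs(tab$disparity))]
  expect_equal(which.max(tab$unity), which(tab$disparity == 0))
  expect_true(all(diff(u) <= 1e-12))
})
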