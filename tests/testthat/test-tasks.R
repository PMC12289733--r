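test_that("default task protocols carry the experiment designs", {
  sp <- default_task("implicit_spatial")
  expect_identical(sp$anchor, 45)
  expect_identical(sort(abs(unique(abs(sp$disparities)))), c(3, 6, 12, 24))
  expect_length(sp$disparities, 8L)
  tm <- default_task("explicit_temporal")
  expect_identical(tm$anchor, 160)
  expect_identical(sort(tm$disparities),
                   c(-150, -80, -20, 0, 20, 80, 150, 250))
  expect_error(default_task("implicit_temporal"), "arg")
})

test_that("auditory bias normalizes the shift by the disparity", {
  expect_equal(auditory_bias(45, 45, 51), 0)
  expect_equal(auditory_bias(51, 45, 51), 1)
  expect_equal(auditory_bias(48, 45, 51), 0.5)
  expect_equal(auditory_bias(42, 45, 39), 0.5)  # sign-symmetric
  expect_error(auditory_bias(45, 45, 45), "zero disparity")
})

test_that("task runs honour each model's readout conventions", {
  # forced fusion with equal reliabilities: bias 0.5 everywhere
  tab <- run_task("bci", default_task("implicit_spatial"),
                  params = list(p_common = 1, sigma_a = 5, sigma_v = 5,
                                sigma_p = 1e6))
  expect_equal(tab$bias, rep(0.5, 8), tolerance = 1e-6)
  expect_equal(tab$unity, rep(1, 8))

  # p_common = 0: no unity reports at any onset disparity
  tt <- run_task("bci", default_task("explicit_temporal"),
                 params = list(p_common = 0, sigma_a = 40, sigma_v = 40))
  expect_equal(tt$unity, rep(0, 8))

  # the static integrator cannot run the temporal task
  expect_error(run_task("mle", default_task("explicit_temporal")),
               "static")

  # decoupled three-layer net: unity flat at baseline across disparities
  tab_net <- run_task("net_stci", default_task("explicit_spatial"),
                      params = list(n_neurons = 90, dt = 0.25, w0_mc = 0,
                                    w0_av = 0, w0_va = 0, w0_cm = 0))
  expect_lt(diff(range(tab_net$unity)), 1e-6)
})

test_that("gaussian fits recover known unity curves", {
  d <- default_task("explicit_temporal")$disparities
  exact <- 0.9 * exp(-(d - 5)^2 / (2 * 20^2))
  f <- fit_gaussian(d, exact)
  expect_equal(f$amplitude, 0.9, tolerance = 1e-6)
  expect_equal(f$mean, 5, tolerance = 1e-5)
  expect_equal(f$width, 20, tolerance = 1e-4)
  expect_false(f$degenerate)

  # constant curve: width unidentifiable, flagged
  fc <- fit_gaussian(d, rep(0.4, length(d)))
  expect_true(fc$degenerate)
  expect_equal(fc$amplitude, 0.4)

  # noisy recovery at a fixed seed
  set.seed(99)
  noisy <- pmin(pmax(0.7 * exp(-d^2 / (2 * 10^2)) +
                       stats::rnorm(length(d), 0, 0.02), 0), 1)
  fn <- fit_gaussian(d, noisy)
  expect_equal(fn$amplitude, 0.7, tolerance = 0.05)

  # invariance to point order
  sh <- sample(length(d))
  f2 <- fit_gaussian(d[sh], exact[sh])
  expect_equal(f2$amplitude, f$amplitude, tolerance = 1e-8)
  expect_error(fit_gaussian(1:3, c(0.1, 0.2, 0.3)), "at least 4")
})

test_that("parameter sweeps move the bias in the documented direction", {
  out <- sweep_metric("bci", default_task("implicit_spatial"), "p_common",
                      seq(0.1, 0.9, by = 0.2),
                      params = list(sigma_a = 5, sigma_v = 5,
                                    sigma_p = 10))
  expect_true(all(diff(out$bias_m6) > 0))
  one <- sweep_metric("bci", default_task("explicit_temporal"), "p_common",
                      0.5, params = list(sigma_a = 50, sigma_v = 50,
                                         sigma_p = 60))
  expect_identical(nrow(one), 1L)
  expect_true(all(c("amplitude", "mean", "width") %in% names(one)))
})

test_that("model fitting degenerates gracefully and respects bounds", {
  tk <- default_task("explicit_temporal")
  obs <- run_task("bci", tk, params = list(p_common = 0.6, sigma_a = 40,
                                           sigma_v = 40, sigma_p = 60))
  observed <- data.frame(disparity = obs$disparity, value = obs$unity)

  # zero-parameter fit returns the model's own loss
  z <- fit_model("bci", tk, observed, free_params = list(),
                 params = list(p_common = 0.6, sigma_a = 40, sigma_v = 40,
                               sigma_p = 60))
  expect_equal(z$loss, 0, tolerance = 1e-20)
  expect_identical(z$evals, 1L)

  # bounds excluding the generating value: boundary solution, loss > 0
  b <- fit_model("bci", tk, observed, free_params = list(
    p_common = c(0.8, 1)),
    params = list(sigma_a = 40, sigma_v = 40, sigma_p = 60),
    budget = 60, seed = 4)
  expect_gte(b$par[["p_common"]], 0.8)
  expect_gt(b$loss, 1e-6)
})
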