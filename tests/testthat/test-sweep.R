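test_that("collect_all sweeps preserve counts, order and determinism", {
  cfg <- sweep_config("p_common", c(0, 0.5, 1), base_seed = 11)
  coll <- run_sweep("bci", av_stim(45, 51),
                    list(sigma_a = 4, sigma_v = 4, sigma_p = 10), cfg)
  expect_s3_class(coll, "nd_collection")
  expect_length(coll, 3L)
  expect_identical(coll$sweep_values, c(0, 0.5, 1))

  # posterior limits forced by the prior
  tab <- collection_metric(coll, function(r) r$causes)
  expect_equal(tab$metric[tab$sweep_value == 0], 0)
  expect_equal(tab$metric[tab$sweep_value == 1], 1)

  # noiseless model: repeats are identical
  cfg2 <- sweep_config("p_common", c(0.3, 0.7), repeats = 2, base_seed = 5)
  coll2 <- run_sweep("bci", av_stim(), list(sigma_a = 3, sigma_v = 3), cfg2)
  expect_length(coll2, 4L)
  expect_identical(coll2$results[[1]]$activity, coll2$results[[2]]$activity)
})

test_that("reduce-on-the-fly equals collecting then reducing", {
  metric <- function(r) max(get_mode(r, "multi"))
  cfg_red <- sweep_config("p_common", c(0.2, 0.8), strategy = metric,
                          base_seed = 11)
  cfg_all <- sweep_config("p_common", c(0.2, 0.8), base_seed = 11)
  fixed <- list(sigma_a = 4, sigma_v = 2, sigma_p = 10)
  red <- run_sweep("bci", av_stim(), fixed, cfg_red)
  coll <- run_sweep("bci", av_stim(), fixed, cfg_all)
  expect_identical(names(red), c("value", "repeat", "metric"))
  expect_equal(red$metric, collection_metric(coll, metric)$metric,
               tolerance = 1e-15)

  # also for a network model (2-value smoke sweep)
  cfg_net <- sweep_config("w0_av", c(0, 1.5), strategy = metric,
                          base_seed = 2)
  cfg_net_all <- sweep_config("w0_av", c(0, 1.5), base_seed = 2)
  fixed_net <- list(n_neurons = 90, dt = 0.25)
  red_n <- run_sweep("net_av", av_stim(duration = 80), fixed_net, cfg_net,
                     duration = 100)
  coll_n <- run_sweep("net_av", av_stim(duration = 80), fixed_net,
                      cfg_net_all, duration = 100)
  expect_equal(red_n$metric, collection_metric(coll_n, metric)$metric,
               tolerance = 1e-15)
})

test_that("sweep errors carry coordinates and schema checks fire early", {
  cfg <- sweep_config("not_a_param", c(1, 2))
  expect_error(run_sweep("bci", av_stim(), list(), cfg), "not in model")
  expect_error(sweep_config("p_common", numeric(0)), "non-empty")
  # member failure reports its (value, repeat) coordinates
  cfg2 <- sweep_config("sigma_p", c(5, 10))
  expect_error(
    run_sweep("bci", av_stim(45, 51), list(), cfg2, grid = seq(100, 179)),
    "sigma_p = 5")
})

test_that("cross sweeps produce one ordered disparity curve per value", {
  cfg <- sweep_config("p_common", c(0.2, 0.8), base_seed = 3)
  out <- cross_sweep("bci", av_stim(45, 45),
                     list(sigma_a = 4, sigma_v = 4, sigma_p = 10), cfg,
                     disparities = c(12, -12, 3, -3))
  expect_length(out, 2L)
  expect_identical(out[["0.2"]]$sweep_values, c(-12, -3, 3, 12))
  expect_length(out[["0.2"]]$results, 4L)
  # posterior falls with |disparity| within each curve
  u <- collection_metric(out[["0.8"]], function(r) r$causes)
  expect_lt(u$metric[u$sweep_value == -12], u$metric[u$sweep_value == -3])
})

test_that("collections and reduced tables export to disk and back", {
  cfg <- sweep_config("p_common", c(0.1, 0.9))
  coll <- run_sweep("bci", av_stim(), list(sigma_a = 3, sigma_v = 3), cfg)
  h5 <- tempfile(fileext = ".h5")
  export_result(coll, h5)
  expect_true(file.exists(h5))
  vals <- rhdf5::h5read(h5, "sweep_values")
  expect_equal(as.numeric(vals), c(0.1, 0.9))
  act <- rhdf5::h5read(h5, "member_0001/activity")
  expect_identical(unname(dim(act)),
                   unname(dim(coll$results[[1]]$activity)))
  expect_error(export_result(coll, tempfile(), format = "csv"),
               "tabular export undefined")

  red <- run_sweep("bci", av_stim(), list(sigma_a = 3, sigma_v = 3),
                   sweep_config("p_common", c(0.1, 0.9),
                                strategy = function(r) r$causes))
  csv <- tempfile(fileext = ".csv")
  export_result(red, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(names(back), c("value", "repeat", "metric"))
  expect_equal(back$metric, red$metric)
  unlink(c(h5, csv))
})
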