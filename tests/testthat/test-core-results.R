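make_result <- function(n_time = 10, n_x = 180, modes = 3) {
  labs <- c("auditory", "visual", "multi")[seq_len(modes)]
  act <- stats::setNames(lapply(seq_len(modes), function(i) {
    matrix(i, n_time, n_x)
  }), labs)
  nd_result(act, coords = list(time = seq_len(n_time) - 1,
                               x = seq(0, length.out = n_x)),
            mode_roles = stats::setNames(
              c("unisensory", "unisensory", "multisensory")[seq_len(modes)],
              labs))
}

test_that("nd_result enforces the mode and axis invariants", {
  r <- make_result()
  expect_s3_class(r, "nd_result")
  expect_identical(unname(dim(r$activity)), c(3L, 10L, 180L))
  expect_identical(r$modes, c("auditory", "visual", "multi"))

  # fewer than 2 unisensory modes is rejected
  act <- list(auditory = matrix(1, 2, 3), multi = matrix(1, 2, 3),
              multi2 = matrix(1, 2, 3))
  expect_error(
    nd_result(act, coords = list(time = 1:2, x = 1:3),
              mode_roles = c(auditory = "unisensory",
                             multi = "multisensory",
                             multi2 = "multisensory")),
    "insufficient unisensory|exactly one multisensory")

  # shape mismatch is rejected before anything is stored
  act <- list(auditory = matrix(1, 2, 4), visual = matrix(1, 2, 3),
              multi = matrix(1, 2, 3))
  expect_error(
    nd_result(act, coords = list(time = 1:2, x = 1:3),
              mode_roles = c(auditory = "unisensory", visual = "unisensory",
                             multi = "multisensory")),
    "not match coords")

  # causes outside [0, 1] rejected; non-finite activity rejected
  good <- list(auditory = matrix(1, 2, 3), visual = matrix(1, 2, 3),
               multi = matrix(1, 2, 3))
  roles <- c(auditory = "unisensory", visual = "unisensory",
             multi = "multisensory")
  expect_error(nd_result(good, list(time = 1:2, x = 1:3), roles,
                         causes = 1.2), "\\[0, 1\\]")
  bad <- good; bad$multi[1, 1] <- NaN
  expect_error(nd_result(bad, list(time = 1:2, x = 1:3), roles),
               "non-finite")
})

test_that("a full 5-axis result exposes exactly five named axes", {
  act <- stats::setNames(lapply(1:3, function(i) {
    array(i, dim = c(4, 5, 3, 2))
  }), c("auditory", "visual", "multi"))
  r <- nd_result(act,
                 coords = list(time = 1:4, x = 1:5, y = 1:3, z = 1:2),
                 mode_roles = c(auditory = "unisensory",
                                visual = "unisensory",
                                multi = "multisensory"))
  expect_identical(length(dim(r$activity)), 5L)
  expect_identical(names(r$coords), c("time", "x", "y", "z"))
  m <- get_mode(r, "multi")
  expect_identical(unname(dim(m)), c(4L, 5L, 3L, 2L))
})

test_that("get_mode extracts one mode and rejects unknown labels", {
  r <- make_result()
  a <- get_mode(r, "auditory")
  expect_identical(unname(dim(a)), c(10L, 180L))
  expect_true(all(a == 1))
  expect_true(all(get_mode(r, "multi") == 3))
  expect_error(get_mode(r, "olfactory"), "unknown mode")
})

test_that("stack_collection validates homogeneity and ordering", {
  rs <- lapply(1:3, function(i) make_result())
  coll <- stack_collection(rs, "p_common", c(0, 0.5, 1))
  expect_s3_class(coll, "nd_collection")
  expect_length(coll, 3L)
  expect_identical(coll$sweep_values, c(0, 0.5, 1))

  expect_error(stack_collection(list(), "p", numeric(0)), "empty")
  expect_error(stack_collection(rs, "p", c(0, 1)), "3 results but 2")
  other <- make_result(n_x = 90)
  expect_error(stack_collection(c(rs[1:2], list(other)), "p", 1:3),
               "heterogeneous|different coordinate")
})

test_that("collection_metric preserves order and reports failures", {
  rs <- lapply(1:3, function(i) make_result())
  coll <- stack_collection(rs, "p_common", c(0, 0.5, 1))
  tab <- collection_metric(coll, function(r) max(get_mode(r, "multi")))
  expect_identical(tab$sweep_value, c(0, 0.5, 1))
  expect_identical(tab$metric, c(3, 3, 3))

  # constant metric
  expect_true(all(collection_metric(coll, function(r) 0)$metric == 0))

  # order equivalence with member-by-member mapping
  f <- function(r) sum(get_mode(r, "auditory"))
  expect_identical(collection_metric(coll, f)$metric,
                   vapply(coll$results, f, numeric(1)))

  # failure carries the member's sweep value
  boom <- function(r) if (TRUE) stop("bad member")
  expect_error(collection_metric(coll, boom), "p_common = 0.*bad member")
})

test_that("HDF5 export round-trips activity bit-identically", {
  r <- run_model("bci", av_stim(45, 51),
                 list(p_common = 0.4, sigma_a = 3, sigma_v = 2))
  path <- tempfile(fileext = ".h5")
  write_result(r, path)
  back <- read_result(path)
  expect_identical(back$activity, r$activity)
  expect_identical(back$coords, r$coords)
  expect_identical(back$causes, r$causes)
  expect_identical(back$metadata$params, r$metadata$params)
  unlink(path)
})
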