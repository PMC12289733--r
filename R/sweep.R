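#' Configure a parameter sweep
#'
#' @param parameter name of the swept model parameter (must exist in the
#'   model's schema).
#' @param values ordered vector of parameter values (non-empty).
#' @param repeats runs per value (>= 1); repeats differ only through their
#'   derived child seeds.
#' @param base_seed integer from which every run's child seed is derived
#'   deterministically, so sequential and parallel execution agree.
#' @param strategy `"collect_all"` to keep every result in an
#'   [stack_collection()], or a metric function `nd_result -> scalar` to
#'   reduce each result on the fly and release it (constant memory in the
#'   number of sweep values).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(parameter, values, repeats = 1L, base_seed = 1L,
                         strategy = "collect_all") {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  stopifnot(repeats >= 1L)
  if (!identical(strategy, "collect_all") && !is.function(strategy)) {
    stop("strategy must be \"collect_all\" or a metric function",
         call. = FALSE)
  }
  structure(list(parameter = parameter, values = values,
                 repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed), strategy = strategy),
            class = "sweep_config")
}

#' Run a parameter sweep over a model
#'
#' Runs the model once per (value, repeat) pair, ordered by value then
#' repeat, with the child seed for pair `(i, r)` derived from
#' `config$base_seed` by a stable hash. With the `"collect_all"` strategy
#' the output is an [stack_collection()]; with a metric function it is a
#' data.frame `(value, repeat, metric)` and no result is retained.
#' Any member failure is reported with its (value, repeat) coordinates.
#'
#' @param model contract or registered model name.
#' @param stimuli list of [stimulus()] objects.
#' @param fixed_params named list of parameters held fixed.
#' @param config an [sweep_config()].
#' @param ... passed to [run_model()] (e.g. `duration`, `grid`).
#' @return An `nd_collection` or a data.frame, per the strategy.
#' @export
run_sweep <- function(model, stimuli, fixed_params = list(), config, ...) {
  stopifnot(inherits(config, "sweep_config"))
  contract <- get_contract(model)
  if (!config$parameter %in% contract$param_schema$name) {
    stop(sprintf("parameter '%s' not in model '%s' schema", config$parameter,
                 contract$name), call. = FALSE)
  }
  collect <- identical(config$strategy, "collect_all")
  results <- if (collect) vector("list",
                                 length(config$values) * config$repeats)
  rows <- if (!collect) vector("list",
                               length(config$values) * config$repeats)
  k <- 0L
  for (i in seq_along(config$values)) {
    for (r in seq_len(config$repeats)) {
      k <- k + 1L
      params <- fixed_params
      params[[config$parameter]] <- config$values[i]
      seed <- child_seed(config$base_seed, i, r)
      res <- tryCatch(
        run_model(contract, stimuli, params, seed = seed, ...),
        error = function(e) {
          stop(sprintf("sweep member failed at %s = %s (repeat %d): %s",
                       config$parameter, format(config$values[i]), r,
                       conditionMessage(e)), call. = FALSE)
        })
      if (collect) {
        results[[k]] <- res
      } else {
        rows[[k]] <- data.frame(value = config$values[i], repeat_ = r,
                                metric = as.numeric(config$strategy(res))[1L])
      }
    }
  }
  if (collect) {
    stack_collection(results, sweep_axis = config$parameter,
                     sweep_values = rep(config$values,
                                        each = config$repeats))
  } else {
    out <- do.call(rbind, rows)
    names(out) <- c("value", "repeat", "metric")
    out
  }
}

#' Sweep a parameter across a disparity axis
#'
#' For each parameter value, runs a full disparity curve (one run per
#' disparity, the visual stimulus displaced by the disparity relative to
#' the supplied stimuli) and returns the runs ordered (value, disparity).
#'
#' @inheritParams run_sweep
#' @param disparities numeric vector of signed offsets applied to the
#'   second (visual) stimulus position (deg).
#' @return A list with one [stack_collection()] (sweep axis `"disparity"`)
#'   per parameter value, named by the values.
#' @export
cross_sweep <- function(model, stimuli, fixed_params = list(), config,
                        disparities, ...) {
  stopifnot(inherits(config, "sweep_config"), length(disparities) >= 1L)
  contract <- get_contract(model)
  out <- vector("list", length(config$values))
  names(out) <- as.character(config$values)
  for (i in seq_along(config$values)) {
    params <- fixed_params
    params[[config$parameter]] <- config$values[i]
    runs <- vector("list", length(disparities))
    ord <- order(disparities)
    for (j in seq_along(disparities)) {
      d <- disparities[ord[j]]
      stim <- stimuli
      stim[[2L]]$position <- stimuli[[2L]]$position + d
      seed <- child_seed(config$base_seed, i, j)
      runs[[j]] <- run_model(contract, stim, params, seed = seed, ...)
    }
    out[[i]] <- stack_collection(runs, sweep_axis = "disparity",
                                 sweep_values = disparities[ord])
  }
  out
}
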