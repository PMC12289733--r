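#' Default causal-inference task protocols
#'
#' Three ventriloquist-paradigm experiments are built in. The spatial tasks
#' anchor the auditory stimulus at 45 degrees and place the visual stimulus
#' at signed disparities of +/-3, +/-6, +/-12 and +/-24 degrees; the
#' implicit variant reads out the auditory position estimate (auditory
#' bias), the explicit variant the unity judgment. The temporal task
#' anchors the visual onset at 160 ms and presents the auditory stimulus at
#' onsets of 0, +/-20, +/-80, +/-150 and +250 ms relative to it, with both
#' stimuli co-located at 90 degrees. Every condition is presented once with
#' all noise sources eliminated.
#'
#' @param kind one of `"implicit_spatial"`, `"explicit_spatial"`,
#'   `"explicit_temporal"`.
#' @return A list of class `task_spec` with fields `kind`, `anchor`,
#'   `disparities`, `duration` (stimulus duration, ms), `trial_duration`
#'   (simulated time, ms), `intensity`, `noise` and `position` (temporal
#'   task only).
#' @export
default_task <- function(kind = c("implicit_spatial", "explicit_spatial",
                                  "explicit_temporal")) {
  kind <- match.arg(kind)
  spec <- if (kind == "explicit_temporal") {
    list(kind = kind, anchor = 160,
         disparities = c(-150, -80, -20, 0, 20, 80, 150, 250),
         duration = 100, trial_duration = 600, intensity = 1, noise = 0,
         position = 90)
  } else {
    list(kind = kind, anchor = 45,
         disparities = c(-24, -12, -6, -3, 3, 6, 12, 24),
         duration = 250, trial_duration = 250, intensity = 1, noise = 0,
         position = NA_real_)
  }
  structure(spec, class = "task_spec")
}

#' Auditory bias of a position estimate
#'
#' The shift of the auditory estimate toward the visual stimulus, divided
#' by the distance between the two stimuli:
#' `(estimated_a - true_a) / (true_v - true_a)`. 0 means no visual capture,
#' 1 full capture; the sign convention makes positive bias mean attraction
#' toward vision on either side.
#'
#' @param estimated_a decoded auditory position (deg).
#' @param true_a,true_v true stimulus positions (deg), `true_v != true_a`.
#' @return Dimensionless bias.
#' @export
auditory_bias <- function(estimated_a, true_a, true_v) {
  if (any(true_v == true_a)) {
    stop("auditory bias undefined at zero disparity", call. = FALSE)
  }
  (estimated_a - true_a) / (true_v - true_a)
}

# model-specific readout of one run: auditory/visual estimates + unity
task_readout <- function(contract, res) {
  nm <- contract$name
  uni <- res$modes[res$mode_roles == "unisensory"]
  if (nm == "mle") {
    est <- res$metadata$estimates
    list(est_a = est$fused, est_v = est$fused, unity = NA_real_)
  } else if (nm == "bci") {
    est <- res$metadata$estimates
    list(est_a = est[[uni[1L]]], est_v = est[[uni[2L]]],
         unity = res$causes[1L])
  } else {
    ir <- implicit_readout(res)
    unity <- if (!is.null(res$causes)) {
      max(res$causes)
    } else {
      causal_readout(get_mode(res, res$modes[res$mode_roles ==
                                               "multisensory"])[, ])$peak
    }
    list(est_a = ir[[1L]], est_v = ir[[2L]], unity = unity)
  }
}

#' Run a causal-inference task protocol on a model
#'
#' Presents every condition of the task once (noiseless by default),
#' reading out the model's implicit position estimate (fused or
#' model-averaged estimate for the closed-form models, layer barycenter for
#' the networks) and its unity value (posterior probability of a common
#' cause for the Bayesian model, peak causal readout for the networks; the
#' maximum-likelihood integrator has no unity readout and reports `NA`).
#'
#' @param model contract or registered model name.
#' @param task a [default_task()] or compatible `task_spec`.
#' @param params named list of model parameter overrides.
#' @param ... passed to [run_model()] (e.g. `grid`, `strategy`).
#' @return A data.frame with one row per disparity: `disparity`, `est_a`,
#'   `est_v`, `bias` (spatial tasks; `NA` at zero disparity), `unity`.
#' @export
run_task <- function(model, task, params = list(), ...) {
  contract <- get_contract(model)
  stopifnot(inherits(task, "task_spec"))
  temporal <- task$kind == "explicit_temporal"
  if (temporal && !"time" %in% contract$dimensions) {
    stop(sprintf("model '%s' is static: temporal task undefined",
                 contract$name), call. = FALSE)
  }
  rows <- lapply(task$disparities, function(d) {
    if (temporal) {
      stim <- list(
        stimulus(contract$modalities[1L], position = task$position,
                 onset = task$anchor + d, duration = task$duration,
                 intensity = task$intensity, noise = task$noise),
        stimulus(contract$modalities[2L], position = task$position,
                 onset = task$anchor, duration = task$duration,
                 intensity = task$intensity, noise = task$noise))
    } else {
      stim <- list(
        stimulus(contract$modalities[1L], position = task$anchor,
                 onset = 0, duration = task$duration,
                 intensity = task$intensity, noise = task$noise),
        stimulus(contract$modalities[2L], position = task$anchor + d,
                 onset = 0, duration = task$duration,
                 intensity = task$intensity, noise = task$noise))
    }
    args <- list(contract, stim, params, seed = NULL, ...)
    if (contract$name %in% c("net_av", "net_stci")) {
      args$duration <- task$trial_duration
    } else if (temporal) {
      args$dimension <- "time"
    }
    res <- do.call(run_model, args)
    ro <- task_readout(contract, res)
    bias <- if (temporal || d == 0) NA_real_ else
      auditory_bias(ro$est_a, task$anchor, task$anchor + d)
    data.frame(disparity = d, est_a = ro$est_a, est_v = ro$est_v,
               bias = bias, unity = ro$unity)
  })
  do.call(rbind, rows)
}

#' Fit a Gaussian to a unity-judgment curve
#'
#' Least-squares fit of `P(delta) = A exp(-(delta - mu)^2 / (2 w^2))` to
#' the proportion of common-source reports as a function of audio-visual
#' disparity, the standard summary of explicit causal-inference curves:
#' `amplitude` is the maximum proportion of common-source reports, `mean`
#' the disparity of maximal reports, and `width` (SD) the disparity range
#' over which the model tends to report a common source. The optimizer is
#' started from 5 deterministic initial points and the best run is kept.
#'
#' @param disparities numeric vector (>= 4 points, deg or ms).
#' @param proportions matching proportions in \[0, 1\].
#' @return An object of class `gaussian_fit`: list with `amplitude`,
#'   `mean`, `width`, `rss`, `degenerate` (TRUE when the curve is constant
#'   and the width unidentifiable).
#' @export
fit_gaussian <- function(disparities, proportions) {
  stopifnot(length(disparities) == length(proportions))
  if (length(disparities) < 4L) {
    stop("need at least 4 points to fit a Gaussian", call. = FALSE)
  }
  if (any(proportions < 0 | proportions > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (stats::sd(proportions) < 1e-10) {
    return(structure(list(amplitude = mean(proportions), mean = NA_real_,
                          width = NA_real_, rss = 0, degenerate = TRUE),
                     class = "gaussian_fit"))
  }
  span <- diff(range(disparities))
  obj <- function(p) {
    sum((proportions - p[1L] * exp(-(disparities - p[2L])^2 /
                                     (2 * p[3L]^2)))^2)
  }
  lower <- c(0, min(disparities), span * 1e-4)
  upper <- c(1, max(disparities), 2 * span)
  # deterministic multi-start: data-driven first guess plus a fixed design
  starts <- list(
    c(max(proportions), disparities[which.max(proportions)], span / 4),
    c(max(proportions), mean(disparities), span / 2),
    c(0.5, min(disparities) + span / 4, span / 3),
    c(0.5, max(disparities) - span / 4, span / 3),
    c(max(proportions), disparities[which.max(proportions)], span))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("Gaussian fit failed to converge from every start", call. = FALSE)
  }
  structure(list(amplitude = best$par[1L], mean = best$par[2L],
                 width = best$par[3L], rss = best$value, degenerate = FALSE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<gaussian_fit> degenerate (constant %.3f)\n", x$amplitude))
  } else {
    cat(sprintf("<gaussian_fit> A=%.4f mu=%.3f w=%.3f (rss %.3g)\n",
                x$amplitude, x$mean, x$width, x$rss))
  }
  invisible(x)
}

#' Sweep a parameter and summarize its effect on a task
#'
#' For implicit tasks, reports the auditory bias at the -6 degree disparity
#' point for each parameter value; for explicit tasks, fits a Gaussian to
#' the unity curve at each value and reports its amplitude, mean and width.
#'
#' @inheritParams run_task
#' @param parameter swept parameter name.
#' @param values parameter values, in sweep order.
#' @return A data.frame with one row per value: `value` and `bias_m6` for
#'   implicit tasks, or `value`, `amplitude`, `mean`, `width` for explicit
#'   tasks.
#' @export
sweep_metric <- function(model, task, parameter, values, params = list(),
                         ...) {
  stopifnot(inherits(task, "task_spec"), length(values) >= 1L)
  implicit <- task$kind == "implicit_spatial"
  if (implicit && !(-6 %in% task$disparities)) {
    stop("bias metric requires -6 among the task disparities", call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    p <- params
    p[[parameter]] <- v
    tab <- run_task(model, task, params = p, ...)
    if (implicit) {
      data.frame(value = v, bias_m6 = tab$bias[tab$disparity == -6])
    } else {
      fit <- fit_gaussian(tab$disparity, tab$unity)
      data.frame(value = v, amplitude = fit$amplitude, mean = fit$mean,
                 width = fit$width)
    }
  })
  do.call(rbind, rows)
}

#' Differential-evolution global minimizer
#'
#' A compact seeded differential-evolution search (rand/1/bin scheme) used
#' by [fit_model()]: a uniformly initialized population evolves by mutation
#' (`f_weight`) and binomial crossover (`crossover`), truncating proposals
#' at the bounds, until the evaluation budget is exhausted.
#'
#' @param fn objective function of a numeric parameter vector.
#' @param lower,upper finite bounds (same length).
#' @param budget maximum number of objective evaluations.
#' @param seed integer seed.
#' @param pop_size population size (default `10 * length(lower)`,
#'   minimum 8).
#' @param f_weight mutation factor.
#' @param crossover crossover probability.
#' @return List with `par`, `value`, `evals`.
#' @export
de_optimize <- function(fn, lower, upper, budget = 2000, seed = 1,
                        pop_size = NULL, f_weight = 0.8, crossover = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  if (is.null(pop_size)) pop_size <- max(8L, 10L * d)
  with_seed(seed, {
    pop <- matrix(0, pop_size, d)
    for (j in seq_len(d)) {
      pop[, j] <- stats::runif(pop_size, lower[j], upper[j])
    }
    vals <- apply(pop, 1L, fn)
    evals <- pop_size
    while (evals + 1L <= budget) {
      for (i in seq_len(pop_size)) {
        if (evals >= budget) break
        idx <- sample(setdiff(seq_len(pop_size), i), 3L)
        mutant <- pop[idx[1L], ] + f_weight * (pop[idx[2L], ] -
                                                 pop[idx[3L], ])
        mutant <- pmin(pmax(mutant, lower), upper)
        cross <- stats::runif(d) < crossover
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        v <- fn(trial)
        evals <- evals + 1L
        if (v <= vals[i]) {
          pop[i, ] <- trial
          vals[i] <- v
        }
      }
    }
    best <- which.min(vals)
    list(par = pop[best, ], value = vals[best], evals = evals)
  })
}

#' Fit model parameters to observed task responses
#'
#' Minimizes the sum of squared errors between the model's task outputs
#' (auditory bias for the implicit task, unity proportion for the explicit
#' tasks) and an observed response table, using the seeded
#' differential-evolution search of [de_optimize()]. If the budget is
#' exhausted without improving on the initial population, the best initial
#' member is returned (reported, not raised).
#'
#' @inheritParams run_task
#' @param observed data.frame with columns `disparity` and `value`
#'   covering the task's disparities.
#' @param free_params named list mapping each free parameter to
#'   `c(lower, upper)` finite bounds.
#' @param budget maximum objective evaluations (each is one full task run).
#' @param seed integer seed for the search.
#' @return List with `par` (named best parameters), `loss` (SSE), `evals`.
#' @export
fit_model <- function(model, task, observed, free_params,
                      params = list(), budget = 2000, seed = 1, ...) {
  stopifnot(is.data.frame(observed),
            all(c("disparity", "value") %in% names(observed)))
  if (!all(task$disparities %in% observed$disparity)) {
    stop("observed data must cover the task's disparities", call. = FALSE)
  }
  obs <- observed$value[match(task$disparities, observed$disparity)]
  use_bias <- task$kind == "implicit_spatial"
  predict_col <- function(tab) if (use_bias) tab$bias else tab$unity
  loss_for <- function(p) {
    tab <- run_task(model, task, params = p, ...)
    pred <- predict_col(tab)
    ok <- !is.na(pred) & !is.na(obs)
    sum((pred[ok] - obs[ok])^2)
  }
  if (length(free_params) == 0L) {
    return(list(par = stats::setNames(numeric(0), character(0)),
                loss = loss_for(params), evals = 1L))
  }
  nm <- names(free_params)
  lower <- vapply(free_params, `[`, numeric(1), 1L)
  upper <- vapply(free_params, `[`, numeric(1), 2L)
  stopifnot(all(is.finite(lower)), all(is.finite(upper)))
  fn <- function(x) {
    p <- params
    p[nm] <- as.list(x)
    loss_for(p)
  }
  res <- de_optimize(fn, lower, upper, budget = budget, seed = seed)
  list(par = stats::setNames(res$par, nm), loss = res$value,
       evals = res$evals)
}
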