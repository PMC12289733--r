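#' Parameters of the two-layer audio-visual rate network
#'
#' The network consists of two rings of rate-coded neurons (auditory and
#' visual), each spatially organized with one preferred position per neuron,
#' Mexican-hat lateral connectivity within a ring (short-range excitation
#' `l_ex, sigma_ex` minus longer-range inhibition `l_in, sigma_in`), and
#' Gaussian excitatory cross-modal synapses between rings (`w0_av` is the
#' amplitude of visual-to-auditory coupling, `w0_va` the reverse,
#' `sigma_c` the kernel width). Each neuron's rate follows first-order
#' dynamics through a sigmoid `F(q) = 1 / (1 + exp(-slope (q - theta)))`
#' integrated with a fixed-step Euler scheme. Spatial estimates are decoded
#' as the barycenter of each ring's activity.
#'
#' External stimuli enter as Gaussian bumps of amplitude
#' `intensity * e0_<modality>` and width `sigma_stim_<modality>` centred on
#' the stimulus position, active between onset and onset + duration.
#' Auditory input is broad and fast (`sigma_stim_a`, `tau_a`), visual input
#' narrow and slower (`sigma_stim_v`, `tau_v`), mirroring the physiology of
#' the two modalities. Default amplitudes put a unisensory stimulus just
#' above the sigmoid threshold so that cross-modal convergence is visibly
#' superadditive near threshold (inverse effectiveness).
#'
#' @param n_neurons neurons per ring (default 180, i.e. 1 degree/neuron on a
#'   180-degree ring).
#' @param l_ex,sigma_ex lateral excitation amplitude and width (deg).
#' @param l_in,sigma_in lateral inhibition amplitude and width (deg).
#' @param w0_av,w0_va cross-modal amplitudes (visual->auditory and
#'   auditory->visual).
#' @param sigma_c cross-modal kernel width (deg).
#' @param slope,theta sigmoid slope and threshold.
#' @param tau_a,tau_v membrane time constants (ms).
#' @param dt Euler step (ms); must satisfy `dt <= min(tau)/10`.
#' @param e0_a,e0_v input gain per modality.
#' @param sigma_stim_a,sigma_stim_v input bump widths (deg).
#' @param noise_frac fractional SD of the per-neuron multiplicative input
#'   perturbation (drawn once per trial).
#' @param ... overrides collected into the parameter list (used by the
#'   three-layer extension).
#' @return Named list of class `av_net_params`.
#' @export
av_net_params <- function(n_neurons = 180L, l_ex = 5, sigma_ex = 3,
                          l_in = 4, sigma_in = 24, w0_av = 1.5, w0_va = 1.5,
                          sigma_c = 5, slope = 0.4, theta = 25,
                          tau_a = 3, tau_v = 15, dt = 0.1,
                          e0_a = 33, e0_v = 32,
                          sigma_stim_a = 32, sigma_stim_v = 4,
                          noise_frac = 0, ...) {
  p <- c(as.list(environment()), list(...))
  p$n_neurons <- as.integer(n_neurons)
  if (p$n_neurons < 3L) stop("n_neurons must be >= 3", call. = FALSE)
  pos <- c("sigma_ex", "sigma_in", "sigma_c", "slope", "tau_a", "tau_v",
           "dt", "e0_a", "e0_v", "sigma_stim_a", "sigma_stim_v")
  for (nm in pos) {
    if (p[[nm]] <= 0) stop(sprintf("%s must be > 0", nm), call. = FALSE)
  }
  if (p$l_ex < 0 || p$l_in < 0 || p$w0_av < 0 || p$w0_va < 0 ||
      p$noise_frac < 0) {
    stop("amplitudes and noise_frac must be >= 0", call. = FALSE)
  }
  if (p$dt > min(p$tau_a, p$tau_v) / 10) {
    stop("dt must be <= min(tau)/10 for a stable Euler scheme",
         call. = FALSE)
  }
  class(p) <- "av_net_params"
  p
}

# circular distance matrix (degrees) on an n-neuron ring covering `span` deg
ring_distance <- function(n, span = 180) {
  spacing <- span / n
  p <- (seq_len(n) - 1L) * spacing
  d <- abs(outer(p, p, "-"))
  pmin(d, span - d)
}

# circular distance of grid positions to a point
ring_dist_to <- function(positions, at, span = 180) {
  d <- abs(positions - at)
  pmin(d, span - d)
}

#' Lateral (within-ring) Mexican-hat weight matrix
#'
#' `L[j, k] = l_ex exp(-d^2 / (2 sigma_ex^2)) - l_in exp(-d^2 /
#' (2 sigma_in^2))` with circular distance `d` and no self-connection
#' (zero diagonal).
#'
#' @param params an [av_net_params()] (multisensory-layer variants pass
#'   their own amplitudes via `prefix = "c"`).
#' @param prefix `""` for the unisensory kernel, `"c"` for the multisensory
#'   layer kernel of the three-layer network.
#' @return `n_neurons x n_neurons` symmetric matrix with zero diagonal.
#' @export
build_lateral_weights <- function(params, prefix = "") {
  g <- function(nm, alt) {
    v <- params[[if (prefix == "") nm else paste0(nm, "_c")]]
    if (is.null(v)) alt else v
  }
  l_ex <- g("l_ex", params$l_ex); sigma_ex <- g("sigma_ex", params$sigma_ex)
  l_in <- g("l_in", params$l_in); sigma_in <- g("sigma_in", params$sigma_in)
  if (sigma_in <= sigma_ex && l_in >= l_ex) {
    warning("inhibition dominates excitation at all distances", call. = FALSE)
  }
  d <- ring_distance(params$n_neurons)
  w <- l_ex * exp(-d^2 / (2 * sigma_ex^2)) -
    l_in * exp(-d^2 / (2 * sigma_in^2))
  diag(w) <- 0
  w
}

#' Cross-modal Gaussian weight matrices
#'
#' `W[j, k] = w0 exp(-d^2 / (2 sigma_c^2))`, all entries non-negative;
#' `w_av` feeds visual activity into the auditory ring, `w_va` the reverse.
#'
#' @param params an [av_net_params()].
#' @return List with matrices `w_av` and `w_va`.
#' @export
build_crossmodal_weights <- function(params) {
  d <- ring_distance(params$n_neurons)
  k <- exp(-d^2 / (2 * params$sigma_c^2))
  list(w_av = params$w0_av * k, w_va = params$w0_va * k)
}

#' External input vector for one stimulus
#'
#' Gaussian bump `intensity * e0 * exp(-d(p_j, position)^2 /
#' (2 sigma_stim^2))` on the ring, active for
#' `onset <= t < onset + duration`, with an optional per-neuron
#' multiplicative perturbation `(1 + eta_j)`, `eta_j ~ N(0, noise_frac)`,
#' drawn once per trial (pass the drawn vector via `perturb`).
#'
#' @param stim an [stimulus()].
#' @param params an [av_net_params()].
#' @param t current time (ms).
#' @param perturb optional length-`n_neurons` multiplicative factor vector.
#' @return Numeric vector of length `n_neurons`.
#' @export
external_input <- function(stim, params, t, perturb = NULL) {
  n <- params$n_neurons
  spacing <- 180 / n
  positions <- (seq_len(n) - 1L) * spacing
  if (stim$position < 0 || stim$position >= 180) {
    stop("position outside the [0, 180) degree ring", call. = FALSE)
  }
  if (t < stim$onset || t >= stim$onset + stim$duration) {
    return(numeric(n))
  }
  mod <- stim$modality
  e0 <- params[[paste0("e0_", substr(mod, 1, 1))]]
  sg <- params[[paste0("sigma_stim_", substr(mod, 1, 1))]]
  if (is.null(e0) || is.null(sg)) {
    stop(sprintf("no input gain configured for modality '%s'", mod),
         call. = FALSE)
  }
  d <- ring_dist_to(positions, stim$position)
  e <- stim$intensity * e0 * exp(-d^2 / (2 * sg^2))
  if (!is.null(perturb)) e <- e * perturb
  e
}

# sigmoid activation
net_sigmoid <- function(q, params) {
  1 / (1 + exp(-params$slope * (q - params$theta)))
}

#' One Euler step of the two-layer dynamics
#'
#' For each layer, the net input of neuron `j` is the external input plus
#' the lateral input from its own ring plus the cross-modal input from the
#' other ring; the rate relaxes toward the sigmoid of that input with the
#' layer's time constant: `z <- z + (dt / tau) (-z + F(q))`.
#'
#' @param state list with numeric vectors `z_a`, `z_v` and scalar `t` (ms).
#' @param inputs list with external input vectors `e_a`, `e_v`.
#' @param params an [av_net_params()].
#' @param weights optional precomputed weights (list `l`, `w_av`, `w_va`);
#'   built from `params` when missing.
#' @return Updated state (rates stay within \[0, 1)).
#' @export
step_dynamics <- function(state, inputs, params, weights = NULL) {
  if (is.null(weights)) {
    weights <- list(l = build_lateral_weights(params))
    weights <- c(weights, build_crossmodal_weights(params))
  }
  q_a <- inputs$e_a + as.vector(weights$l %*% state$z_a) +
    as.vector(weights$w_av %*% state$z_v)
  q_v <- inputs$e_v + as.vector(weights$l %*% state$z_v) +
    as.vector(weights$w_va %*% state$z_a)
  z_a <- state$z_a + (params$dt / params$tau_a) *
    (-state$z_a + net_sigmoid(q_a, params))
  z_v <- state$z_v + (params$dt / params$tau_v) *
    (-state$z_v + net_sigmoid(q_v, params))
  if (any(!is.finite(z_a)) || any(!is.finite(z_v))) {
    bad <- which(!is.finite(c(z_a, z_v)))[1L]
    stop(sprintf("non-finite rate at t = %g ms (neuron index %d)",
                 state$t, (bad - 1L) %% params$n_neurons + 1L),
         call. = FALSE)
  }
  list(z_a = z_a, z_v = z_v, t = state$t + params$dt)
}

#' Barycenter (activity-weighted mean position) readout
#'
#' @param activity non-negative activity vector (at least one strictly
#'   positive entry).
#' @param positions preferred positions (deg), same length.
#' @return Decoded position in degrees.
#' @export
barycenter_readout <- function(activity, positions) {
  stopifnot(length(activity) == length(positions))
  s <- sum(activity)
  if (s <= 0 || all(activity == 0)) {
    stop("no activity to read out", call. = FALSE)
  }
  sum(positions * activity) / s
}

# draw the once-per-trial multiplicative input perturbations
input_perturbations <- function(stimuli, params) {
  lapply(stimuli, function(s) {
    frac <- if (s$noise > 0) s$noise else params$noise_frac
    if (frac > 0) 1 + stats::rnorm(params$n_neurons, 0, frac)
    else rep(1, params$n_neurons)
  })
}

#' Simulate the two-layer audio-visual network
#'
#' Runs the Euler dynamics for `duration` ms and returns an [nd_result()]
#' with modes `(auditory, visual, multi)` over a decimated time axis and the
#' ring positions as the `x` axis. This two-layer model has no multisensory
#' layer; its `multi` mode is the mean of the two layer activities
#' (a documented surrogate) and no causal readout is attached.
#'
#' @param stimuli list of [stimulus()] objects (auditory and visual).
#' @param params an [av_net_params()].
#' @param duration total simulated time (ms). The default 500 ms leaves
#'   ample post-stimulus settling (>= 5 max(tau)) for the default task
#'   stimuli.
#' @param seed integer seed for the input perturbations (only relevant when
#'   a noise source is non-zero).
#' @param store_dt time resolution (ms) of the stored trajectories; the
#'   final step is always stored.
#' @return An [nd_result()].
#' @export
simulate_av <- function(stimuli, params = av_net_params(), duration = 500,
                        seed = NULL, store_dt = 1) {
  sim <- simulate_av_engine(stimuli, params, duration, seed, store_dt)
  n <- params$n_neurons
  positions <- (seq_len(n) - 1L) * (180 / n)
  labs <- vapply(stimuli[1:2], `[[`, character(1), "modality")
  act <- stats::setNames(
    list(t(sim$z_a), t(sim$z_v), t((sim$z_a + sim$z_v) / 2)),
    c(labs, "multi"))
  mode_roles <- stats::setNames(
    c("unisensory", "unisensory", "multisensory"), names(act))
  nd_result(act, coords = list(time = sim$times, x = positions),
            mode_roles = mode_roles,
            metadata = list(engine = "av", dt = params$dt,
                            duration = duration))
}

# core Euler loop shared contractually with the three-layer model: returns
# decimated trajectories (n_neurons x n_stored) and stored times
simulate_av_engine <- function(stimuli, params, duration, seed, store_dt) {
  n <- params$n_neurons
  l <- build_lateral_weights(params)
  cw <- build_crossmodal_weights(params)
  pert <- with_seed(seed, input_perturbations(stimuli, params))
  n_steps <- ceiling(duration / params$dt)
  keep_every <- max(1L, round(store_dt / params$dt))
  keep <- unique(c(seq(1L, n_steps + 1L, by = keep_every), n_steps + 1L))
  keep_flag <- logical(n_steps + 1L); keep_flag[keep] <- TRUE
  z_a <- numeric(n); z_v <- numeric(n)
  Z_a <- matrix(0, n, length(keep)); Z_v <- matrix(0, n, length(keep))
  times <- numeric(length(keep))
  ki <- 1L
  s_a <- stimuli[[1L]]; s_v <- stimuli[[2L]]
  prof_a <- external_input(s_a, params,
                           t = s_a$onset, perturb = pert[[1L]])
  prof_v <- external_input(s_v, params,
                           t = s_v$onset, perturb = pert[[2L]])
  dt <- params$dt
  for (step in 0:n_steps) {
    t <- step * dt
    if (keep_flag[step + 1L]) {
      Z_a[, ki] <- z_a; Z_v[, ki] <- z_v; times[ki] <- t
      ki <- ki + 1L
    }
    if (step == n_steps) break
    e_a <- if (t >= s_a$onset && t < s_a$onset + s_a$duration) prof_a else 0
    e_v <- if (t >= s_v$onset && t < s_v$onset + s_v$duration) prof_v else 0
    q_a <- e_a + as.vector(l %*% z_a) + as.vector(cw$w_av %*% z_v)
    q_v <- e_v + as.vector(l %*% z_v) + as.vector(cw$w_va %*% z_a)
    z_a <- z_a + (dt / params$tau_a) * (-z_a + net_sigmoid(q_a, params))
    z_v <- z_v + (dt / params$tau_v) * (-z_v + net_sigmoid(q_v, params))
    if (any(!is.finite(z_a)) || any(!is.finite(z_v))) {
      stop(sprintf("non-finite rate at t = %g ms", t), call. = FALSE)
    }
  }
  list(z_a = Z_a, z_v = Z_v, times = times)
}

# run entry point for the "net_av" contract
net_av_run_fn <- function(stimuli, params, seed = NULL, duration = 500,
                          ...) {
  p <- do.call(av_net_params, params[!vapply(params, is.na, logical(1))])
  simulate_av(stimuli, p, duration = duration, seed = seed, ...)
}

.net_av_contract <- function(modalities = c("auditory", "visual")) {
  defs <- av_net_params()
  nm <- c("n_neurons", "l_ex", "sigma_ex", "l_in", "sigma_in", "w0_av",
          "w0_va", "sigma_c", "slope", "theta", "tau_a", "tau_v", "dt",
          "e0_a", "e0_v", "sigma_stim_a", "sigma_stim_v", "noise_frac")
  model_contract(
    name = "net_av", modalities = modalities,
    param_schema = data.frame(
      name = nm, default = unlist(defs[nm]),
      lower = c(3, rep(1e-9, 4), 0, 0, 1e-9, 1e-9, -Inf, 1e-9, 1e-9, 1e-9,
                1e-9, 1e-9, 1e-9, 1e-9, 0),
      upper = rep(Inf, length(nm))),
    run = net_av_run_fn, dimensions = c("space", "time"))
}
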