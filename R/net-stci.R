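#' Parameters of the three-layer spatiotemporal causal-inference network
#'
#' Extends the two-layer audio-visual network ([av_net_params()]) with a
#' multisensory layer joined to the unisensory rings by Gaussian
#' feedforward (`w0_mc`, unisensory -> multisensory) and feedback
#' (`w0_cm`, multisensory -> unisensory) synapses of width `sigma_mc`, its
#' own Mexican-hat lateral kernel (`l_ex_c`, `sigma_ex_c`, `l_in_c`,
#' `sigma_in_c`) and time constant `tau_c`. Pathway inputs carry latencies
#' (`delta_cm` on the cross-modal route, `delta_ff` feedforward, `delta_fb`
#' feedback) capturing early versus late multisensory interactions, and
#' first-order temporal filters (`tau_filt_a`, `tau_filt_v`, `tau_filt_c`;
#' 0 disables a filter) reproduce the temporal progression of synaptic
#' input in each neuron population.
#'
#' The causal readout divides the maximal multisensory rate by
#' `causes_norm` (default 1, the sigmoid ceiling), so it is the raw maximal
#' rate interpreted as the proportion of common-source reports.
#'
#' @inheritParams av_net_params
#' @param w0_mc,w0_cm feedforward and feedback amplitudes (>= 0).
#' @param sigma_mc interlayer kernel width (deg).
#' @param l_ex_c,sigma_ex_c,l_in_c,sigma_in_c multisensory lateral kernel.
#' @param tau_c multisensory time constant (ms).
#' @param tau_filt_a,tau_filt_v,tau_filt_c temporal filter time constants
#'   (ms); 0 = no filter.
#' @param delta_cm,delta_ff,delta_fb pathway latencies (ms, >= 0).
#' @param causes_norm normalization constant of the causal readout (> 0).
#' @return Named list of class `stci_params` (also an `av_net_params`).
#' @export
stci_params <- function(w0_mc = 2.0, w0_cm = 2.5, sigma_mc = 5,
                        l_ex_c = 3, sigma_ex_c = 3, l_in_c = 2.6,
                        sigma_in_c = 24, tau_c = 15,
                        tau_filt_a = 10, tau_filt_v = 20, tau_filt_c = 15,
                        delta_cm = 10, delta_ff = 10, delta_fb = 30,
                        causes_norm = 1, ...) {
  extra <- list(w0_mc = w0_mc, w0_cm = w0_cm, sigma_mc = sigma_mc,
                l_ex_c = l_ex_c, sigma_ex_c = sigma_ex_c, l_in_c = l_in_c,
                sigma_in_c = sigma_in_c, tau_c = tau_c,
                tau_filt_a = tau_filt_a, tau_filt_v = tau_filt_v,
                tau_filt_c = tau_filt_c, delta_cm = delta_cm,
                delta_ff = delta_ff, delta_fb = delta_fb,
                causes_norm = causes_norm)
  if (w0_mc < 0 || w0_cm < 0) {
    stop("interlayer amplitudes must be >= 0", call. = FALSE)
  }
  if (any(unlist(extra[c("tau_filt_a", "tau_filt_v", "tau_filt_c",
                         "delta_cm", "delta_ff", "delta_fb")]) < 0)) {
    stop("time constants and latencies must be >= 0", call. = FALSE)
  }
  if (tau_c <= 0 || causes_norm <= 0) {
    stop("tau_c and causes_norm must be > 0", call. = FALSE)
  }
  p <- do.call(av_net_params, c(list(...), extra))
  if (p$dt > p$tau_c / 10) {
    stop("dt must be <= tau_c/10", call. = FALSE)
  }
  class(p) <- c("stci_params", "av_net_params")
  p
}

#' Interlayer (feedforward / feedback) weight matrices
#'
#' Gaussian spatial kernels scaled by `w0_mc` (unisensory -> multisensory)
#' and `w0_cm` (multisensory -> unisensory); the same kernel serves both
#' modalities.
#'
#' @param params an [stci_params()].
#' @return List with matrices `w_mc` and `w_cm`.
#' @export
build_interlayer_weights <- function(params) {
  d <- ring_distance(params$n_neurons)
  k <- exp(-d^2 / (2 * params$sigma_mc^2))
  list(w_mc = params$w0_mc * k, w_cm = params$w0_cm * k)
}

#' First-order temporal filter
#'
#' Low-pass filters a series with `g <- g + (dt / tau) (-g + x)` starting
#' from `g = 0`; `tau = 0` returns the input unchanged. Applied per pathway
#' before inputs are summed in the three-layer network.
#'
#' @param x numeric vector (one value per time step) or matrix
#'   (neurons x time).
#' @param tau_filt filter time constant (ms, >= 0).
#' @param dt time step (ms).
#' @return Filtered series, same shape as `x`.
#' @export
temporal_filter <- function(x, tau_filt, dt) {
  stopifnot(tau_filt >= 0, dt > 0)
  if (tau_filt == 0) return(x)
  a <- dt / tau_filt
  if (is.matrix(x)) {
    g <- matrix(0, nrow(x), ncol(x))
    acc <- numeric(nrow(x))
    for (i in seq_len(ncol(x))) {
      acc <- acc + a * (-acc + x[, i])
      g[, i] <- acc
    }
    g
  } else {
    g <- numeric(length(x))
    acc <- 0
    for (i in seq_along(x)) {
      acc <- acc + a * (-acc + x[i])
      g[i] <- acc
    }
    g
  }
}

#' Delay a pathway series
#'
#' The output at time `t` equals the input at `t - latency` and is zero
#' before the latency has elapsed. Latencies that are not multiples of `dt`
#' round to the nearest step.
#'
#' @param x numeric vector (one value per time step) or matrix
#'   (neurons x time).
#' @param latency delay (ms, >= 0).
#' @param dt time step (ms).
#' @return Delayed series, same shape as `x`.
#' @export
delayed <- function(x, latency, dt) {
  stopifnot(latency >= 0, dt > 0)
  lag <- round(latency / dt)
  if (lag == 0) return(x)
  if (is.matrix(x)) {
    n <- ncol(x)
    out <- matrix(0, nrow(x), n)
    if (lag < n) out[, (lag + 1L):n] <- x[, 1L:(n - lag)]
    out
  } else {
    n <- length(x)
    out <- numeric(n)
    if (lag < n) out[(lag + 1L):n] <- x[1L:(n - lag)]
    out
  }
}

#' Causal readout from multisensory activity
#'
#' Divides the maximal multisensory rate by `causes_norm` and clips to
#' \[0, 1\]; the per-time series is the model's moment-by-moment tendency to
#' report a common source, and its peak over the trial is the trial-level
#' proportion of common-source reports.
#'
#' @param multi_activity matrix (time x space) or vector (one value per
#'   time step) of multisensory activity.
#' @param causes_norm normalization constant (> 0).
#' @return List with `series` (value in \[0, 1\] per time step) and `peak`
#'   (trial-level scalar).
#' @export
causal_readout <- function(multi_activity, causes_norm = 1) {
  stopifnot(causes_norm > 0)
  series <- if (is.matrix(multi_activity)) {
    apply(multi_activity, 1L, max)
  } else {
    as.numeric(multi_activity)
  }
  series <- pmin(pmax(series / causes_norm, 0), 1)
  list(series = series, peak = max(series))
}

#' Implicit (position) readout of a network result
#'
#' Decodes the position estimate of each unisensory layer as the barycenter
#' of its activity at the readout (final stored) time.
#'
#' @param result an [nd_result()] from [simulate_av()] or
#'   [simulate_stci()].
#' @return Named numeric vector with one decoded position (deg) per
#'   unisensory mode.
#' @export
implicit_readout <- function(result) {
  stopifnot(inherits(result, "nd_result"))
  uni <- result$modes[result$mode_roles == "unisensory"]
  tn <- length(result$coords$time)
  out <- vapply(uni, function(m) {
    a <- get_mode(result, m)
    barycenter_readout(a[tn, ], result$coords$x)
  }, numeric(1))
  out
}

#' Simulate the three-layer spatiotemporal causal-inference network
#'
#' Unisensory net input: external + lateral + delayed cross-modal + delayed,
#' filtered feedback from the multisensory layer. Multisensory net input:
#' its own lateral input + delayed, filtered feedforward drive from both
#' unisensory layers. The returned result carries the two unisensory layers
#' and the multisensory layer as modes, plus the causal-readout time series
#' in `causes`.
#'
#' @inheritParams simulate_av
#' @param params an [stci_params()].
#' @return An [nd_result()] with `causes` set to the causal-readout series.
#' @export
simulate_stci <- function(stimuli, params = stci_params(), duration = 500,
                          seed = NULL, store_dt = 1) {
  n <- params$n_neurons
  l <- build_lateral_weights(params)
  l_c <- build_lateral_weights(params, prefix = "c")
  cw <- build_crossmodal_weights(params)
  iw <- build_interlayer_weights(params)
  pert <- with_seed(seed, input_perturbations(stimuli, params))
  dt <- params$dt
  n_steps <- ceiling(duration / dt)
  keep_every <- max(1L, round(store_dt / dt))
  keep <- unique(c(seq(1L, n_steps + 1L, by = keep_every), n_steps + 1L))
  keep_flag <- logical(n_steps + 1L); keep_flag[keep] <- TRUE
  lag_cm <- round(params$delta_cm / dt)
  lag_ff <- round(params$delta_ff / dt)
  lag_fb <- round(params$delta_fb / dt)
  max_lag <- max(lag_cm, lag_ff, lag_fb)
  # ring buffers of past rates for the delayed pathways
  hist_a <- matrix(0, n, max_lag + 1L)
  hist_v <- matrix(0, n, max_lag + 1L)
  hist_c <- matrix(0, n, max_lag + 1L)
  hidx <- function(step, lag) ((step - lag) %% (max_lag + 1L)) + 1L
  z_a <- numeric(n); z_v <- numeric(n); z_c <- numeric(n)
  g_fb_a <- numeric(n); g_fb_v <- numeric(n); g_ff <- numeric(n)
  a_fa <- if (params$tau_filt_a > 0) dt / params$tau_filt_a else NA_real_
  a_fv <- if (params$tau_filt_v > 0) dt / params$tau_filt_v else NA_real_
  a_fc <- if (params$tau_filt_c > 0) dt / params$tau_filt_c else NA_real_
  Z_a <- matrix(0, n, length(keep)); Z_v <- matrix(0, n, length(keep))
  Z_c <- matrix(0, n, length(keep)); times <- numeric(length(keep))
  ki <- 1L
  s_a <- stimuli[[1L]]; s_v <- stimuli[[2L]]
  prof_a <- external_input(s_a, params, t = s_a$onset, perturb = pert[[1L]])
  prof_v <- external_input(s_v, params, t = s_v$onset, perturb = pert[[2L]])
  for (step in 0:n_steps) {
    t <- step * dt
    if (keep_flag[step + 1L]) {
      Z_a[, ki] <- z_a; Z_v[, ki] <- z_v; Z_c[, ki] <- z_c
      times[ki] <- t; ki <- ki + 1L
    }
    if (step == n_steps) break
    cur <- (step %% (max_lag + 1L)) + 1L
    hist_a[, cur] <- z_a; hist_v[, cur] <- z_v; hist_c[, cur] <- z_c
    za_del <- if (step >= lag_ff) hist_a[, hidx(step, lag_ff)] else numeric(n)
    zv_del <- if (step >= lag_ff) hist_v[, hidx(step, lag_ff)] else numeric(n)
    zv_cm <- if (step >= lag_cm) hist_v[, hidx(step, lag_cm)] else numeric(n)
    za_cm <- if (step >= lag_cm) hist_a[, hidx(step, lag_cm)] else numeric(n)
    zc_del <- if (step >= lag_fb) hist_c[, hidx(step, lag_fb)] else numeric(n)
    e_a <- if (t >= s_a$onset && t < s_a$onset + s_a$duration) prof_a else 0
    e_v <- if (t >= s_v$onset && t < s_v$onset + s_v$duration) prof_v else 0
    # feedback pathway: delayed multisensory rates, filtered per modality
    x_fb <- as.vector(iw$w_cm %*% zc_del)
    g_fb_a <- if (is.na(a_fa)) x_fb else g_fb_a + a_fa * (-g_fb_a + x_fb)
    g_fb_v <- if (is.na(a_fv)) x_fb else g_fb_v + a_fv * (-g_fb_v + x_fb)
    # feedforward pathway: delayed unisensory rates, filtered once
    x_ff <- as.vector(iw$w_mc %*% (za_del + zv_del))
    g_ff <- if (is.na(a_fc)) x_ff else g_ff + a_fc * (-g_ff + x_ff)
    q_a <- e_a + as.vector(l %*% z_a) + as.vector(cw$w_av %*% zv_cm) +
      g_fb_a
    q_v <- e_v + as.vector(l %*% z_v) + as.vector(cw$w_va %*% za_cm) +
      g_fb_v
    q_c <- as.vector(l_c %*% z_c) + g_ff
    z_a <- z_a + (dt / params$tau_a) * (-z_a + net_sigmoid(q_a, params))
    z_v <- z_v + (dt / params$tau_v) * (-z_v + net_sigmoid(q_v, params))
    z_c <- z_c + (dt / params$tau_c) * (-z_c + net_sigmoid(q_c, params))
    if (any(!is.finite(z_a)) || any(!is.finite(z_v)) ||
        any(!is.finite(z_c))) {
      stop(sprintf("non-finite rate at t = %g ms", t), call. = FALSE)
    }
  }
  positions <- (seq_len(n) - 1L) * (180 / n)
  cr <- causal_readout(t(Z_c), params$causes_norm)
  labs <- vapply(stimuli[1:2], `[[`, character(1), "modality")
  act <- stats::setNames(list(t(Z_a), t(Z_v), t(Z_c)), c(labs, "multi"))
  mode_roles <- stats::setNames(
    c("unisensory", "unisensory", "multisensory"), names(act))
  nd_result(act, coords = list(time = times, x = positions),
            mode_roles = mode_roles, causes = cr$series,
            metadata = list(engine = "stci", dt = dt, duration = duration,
                            causes_peak = cr$peak))
}

# run entry point for the "net_stci" contract
net_stci_run_fn <- function(stimuli, params, seed = NULL, duration = 500,
                            ...) {
  p <- do.call(stci_params, params[!vapply(params, is.na, logical(1))])
  simulate_stci(stimuli, p, duration = duration, seed = seed, ...)
}

.net_stci_contract <- function(modalities = c("auditory", "visual")) {
  defs <- stci_params()
  nm <- c("n_neurons", "l_ex", "sigma_ex", "l_in", "sigma_in", "w0_av",
          "w0_va", "sigma_c", "slope", "theta", "tau_a", "tau_v", "dt",
          "e0_a", "e0_v", "sigma_stim_a", "sigma_stim_v", "noise_frac",
          "w0_mc", "w0_cm", "sigma_mc", "l_ex_c", "sigma_ex_c", "l_in_c",
          "sigma_in_c", "tau_c", "tau_filt_a", "tau_filt_v", "tau_filt_c",
          "delta_cm", "delta_ff", "delta_fb", "causes_norm")
  low <- stats::setNames(rep(1e-9, length(nm)), nm)
  low[c("w0_av", "w0_va", "noise_frac", "w0_mc", "w0_cm", "tau_filt_a",
        "tau_filt_v", "tau_filt_c", "delta_cm", "delta_ff", "delta_fb")] <- 0
  low["n_neurons"] <- 3; low["theta"] <- -Inf
  model_contract(
    name = "net_stci", modalities = modalities,
    param_schema = data.frame(
      name = nm, default = unlist(defs[nm]), lower = unname(low),
      upper = rep(Inf, length(nm))),
    run = net_stci_run_fn, dimensions = c("space", "time"))
}
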