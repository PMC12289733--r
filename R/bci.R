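#' Bayesian causal inference over one stimulus dimension
#'
#' The Bayesian causal-inference observer explains the ventriloquist effect
#' by inferring whether the auditory and visual measurements `x_a`, `x_v`
#' arise from one common source (`C = 1`, integrate) or two independent
#' sources (`C = 2`, segregate). The generative model assumes
#' `x_m ~ N(s_m, sigma_m)` with source positions drawn from the prior
#' `N(mu_p, sigma_p)`; under `C = 1` a single `s` feeds both measurements.
#' The same machinery applies unchanged to a temporal dimension (onsets in
#' ms).
#'
#' `bci_likelihood_common()` is the marginal density of `(x_v, x_a)` under a
#' shared source; `bci_likelihood_independent()` the product of the two
#' single-source marginals; `bci_posterior_common()` combines them with the
#' prior probability `p_common` of a common cause.
#'
#' @param x_v,x_a visual and auditory measurements (degrees, or ms for the
#'   temporal task).
#' @param params named list with `sigma_a`, `sigma_v`, `sigma_p` (> 0),
#'   `mu_p`, and for the posterior `p_common` in \[0, 1\].
#' @return A density value (likelihoods) or a probability in \[0, 1\]
#'   (posterior).
#' @examples
#' p <- list(sigma_a = 1, sigma_v = 1, sigma_p = 1, mu_p = 0, p_common = 0.5)
#' bci_likelihood_common(0, 0, p)       # 1 / (2 * pi * sqrt(3))
#' bci_posterior_common(0, 0, p)        # ~0.536
#' @export
bci_likelihood_common <- function(x_v, x_a, params) {
  sa2 <- params$sigma_a^2; sv2 <- params$sigma_v^2; sp2 <- params$sigma_p^2
  stopifnot(sa2 > 0, sv2 > 0, sp2 > 0)
  mu <- params$mu_p
  V <- sv2 * sa2 + sv2 * sp2 + sa2 * sp2
  num <- (x_v - x_a)^2 * sp2 + (x_v - mu)^2 * sa2 + (x_a - mu)^2 * sv2
  exp(-num / (2 * V)) / (2 * pi * sqrt(V))
}

#' @rdname bci_likelihood_common
#' @export
bci_likelihood_independent <- function(x_v, x_a, params) {
  sa2 <- params$sigma_a^2; sv2 <- params$sigma_v^2; sp2 <- params$sigma_p^2
  stopifnot(sa2 > 0, sv2 > 0, sp2 > 0)
  mu <- params$mu_p
  stats::dnorm(x_v, mu, sqrt(sv2 + sp2)) *
    stats::dnorm(x_a, mu, sqrt(sa2 + sp2))
}

#' @rdname bci_likelihood_common
#' @export
bci_posterior_common <- function(x_v, x_a, params) {
  pc <- params$p_common
  stopifnot(pc >= 0, pc <= 1)
  l1 <- bci_likelihood_common(x_v, x_a, params)
  l2 <- bci_likelihood_independent(x_v, x_a, params)
  denom <- l1 * pc + l2 * (1 - pc)
  if (denom == 0) {
    if (pc == 0) return(0)
    if (pc == 1) return(1)
    stop("degenerate posterior: both likelihoods are zero", call. = FALSE)
  }
  l1 * pc / denom
}

#' Conditional position estimates under each causal structure
#'
#' Under a common cause the optimal estimate is the precision-weighted mean
#' of both measurements and the prior; under independent causes each
#' modality combines only its own measurement with the prior.
#'
#' @inheritParams bci_likelihood_common
#' @return List with `s_c1` (shared estimate under `C = 1`), `s_a_c2` and
#'   `s_v_c2` (per-modality estimates under `C = 2`).
#' @export
bci_conditional_estimates <- function(x_v, x_a, params) {
  pa <- 1 / params$sigma_a^2; pv <- 1 / params$sigma_v^2
  pp <- 1 / params$sigma_p^2
  mu <- params$mu_p
  list(
    s_c1 = (x_a * pa + x_v * pv + mu * pp) / (pa + pv + pp),
    s_a_c2 = (x_a * pa + mu * pp) / (pa + pp),
    s_v_c2 = (x_v * pv + mu * pp) / (pv + pp))
}

# final per-modality estimates under a readout strategy
bci_final_estimates <- function(x_v, x_a, params,
                                strategy = c("averaging", "selection",
                                             "matching")) {
  strategy <- match.arg(strategy)
  post <- bci_posterior_common(x_v, x_a, params)
  est <- bci_conditional_estimates(x_v, x_a, params)
  w <- switch(strategy,
    averaging = post,
    selection = as.numeric(post > 0.5),
    # probability matching: commit to C = 1 with probability post
    matching = as.numeric(stats::runif(1) < post))
  list(posterior = post,
       s_a = w * est$s_c1 + (1 - w) * est$s_a_c2,
       s_v = w * est$s_c1 + (1 - w) * est$s_v_c2,
       conditionals = est, weight = w)
}

# run entry point for the "bci" contract
bci_run_fn <- function(stimuli, params, seed = NULL, grid = NULL,
                       dimension = c("space", "time"),
                       strategy = "averaging", ...) {
  dimension <- match.arg(dimension)
  a <- stimuli[[1L]]; v <- stimuli[[2L]]
  sa <- params$sigma_a; sv <- params$sigma_v
  if (is.na(sa)) sa <- if (a$noise > 0) a$noise else 3
  if (is.na(sv)) sv <- if (v$noise > 0) v$noise else 3
  true_a <- if (dimension == "space") a$position else a$onset
  true_v <- if (dimension == "space") v$position else v$onset
  noiseless <- is.null(seed) || (a$noise == 0 && v$noise == 0)
  x_a <- if (noiseless) true_a else stats::rnorm(1, true_a, sa)
  x_v <- if (noiseless) true_v else stats::rnorm(1, true_v, sv)
  mu_p <- params$mu_p
  if (is.na(mu_p)) {
    # centered prior: midway between the cues in space, visual onset in time
    mu_p <- if (dimension == "space") (x_a + x_v) / 2 else true_v
  }
  p <- list(sigma_a = sa, sigma_v = sv, sigma_p = params$sigma_p,
            mu_p = mu_p, p_common = params$p_common)
  fin <- bci_final_estimates(x_v, x_a, p, strategy)
  est <- fin$conditionals
  if (is.null(grid)) {
    grid <- if (dimension == "space") seq(0, 179, by = 1) else
      seq(0, 500, by = 2)
  }
  if (min(x_a, x_v) < min(grid) || max(x_a, x_v) > max(grid)) {
    stop("grid does not cover the measurements", call. = FALSE)
  }
  # posterior densities: mixture of the C=1 and C=2 posterior components
  var_c1 <- 1 / (1 / sa^2 + 1 / sv^2 + 1 / p$sigma_p^2)
  var_a2 <- 1 / (1 / sa^2 + 1 / p$sigma_p^2)
  var_v2 <- 1 / (1 / sv^2 + 1 / p$sigma_p^2)
  pi1 <- fin$posterior
  dens_c1 <- .grid_density(grid, est$s_c1, sqrt(var_c1))
  dens_a <- pi1 * dens_c1 + (1 - pi1) *
    .grid_density(grid, est$s_a_c2, sqrt(var_a2))
  dens_v <- pi1 * dens_c1 + (1 - pi1) *
    .grid_density(grid, est$s_v_c2, sqrt(var_v2))
  dens_m <- pi1 * dens_c1 + (1 - pi1) * 0.5 *
    (.grid_density(grid, est$s_a_c2, sqrt(var_a2)) +
       .grid_density(grid, est$s_v_c2, sqrt(var_v2)))
  act <- stats::setNames(list(dens_a, dens_v, dens_m),
                         c(names(stimuli), "multi"))
  mode_roles <- stats::setNames(c("unisensory", "unisensory", "multisensory"),
                                names(act))
  nd_result(act, coords = list(time = 0, x = grid), mode_roles = mode_roles,
            causes = fin$posterior,
            metadata = list(
              dimension = dimension, strategy = strategy,
              measurements = list(x_a = x_a, x_v = x_v),
              resolved = list(sigma_a = sa, sigma_v = sv, mu_p = mu_p),
              estimates = stats::setNames(list(fin$s_a, fin$s_v),
                                          names(stimuli)),
              conditionals = est))
}

.bci_contract <- function(modalities = c("auditory", "visual")) {
  model_contract(
    name = "bci", modalities = modalities,
    param_schema = data.frame(
      name = c("p_common", "sigma_a", "sigma_v", "sigma_p", "mu_p"),
      default = c(0.5, NA_real_, NA_real_, 15, NA_real_),
      lower = c(0, 1e-9, 1e-9, 1e-9, -Inf),
      upper = c(1, Inf, Inf, Inf, Inf)),
    run = bci_run_fn, dimensions = c("space", "time"))
}
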