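#' Reliability weights of the near-optimal bimodal integrator
#'
#' The maximum-likelihood integrator fuses two unisensory position estimates
#' by weighting each with its relative reliability (inverse variance):
#' `w_a = sigma_v^2 / (sigma_a^2 + sigma_v^2)` and symmetrically for `w_v`,
#' so the fused percept leans toward the less variable signal.
#'
#' @param sigma_a,sigma_v standard deviations of the auditory and visual
#'   estimates (same units, > 0).
#' @return Named vector `c(w_a, w_v)`, summing to 1.
#' @examples
#' mle_weights(2, 1)  # vision four times more reliable -> w_v = 0.8
#' @export
mle_weights <- function(sigma_a, sigma_v) {
  if (sigma_a <= 0 || sigma_v <= 0) {
    stop("sigmas must be > 0", call. = FALSE)
  }
  tot <- sigma_a^2 + sigma_v^2
  c(w_a = sigma_v^2 / tot, w_v = sigma_a^2 / tot)
}

#' Fused estimate of the bimodal integrator
#'
#' @param s_hat_a,s_hat_v unisensory estimates (degrees or ms).
#' @param sigma_a,sigma_v their standard deviations (> 0).
#' @return List with `estimate` (the reliability-weighted mean) and `sigma`
#'   (the fused SD, `sqrt(sigma_a^2 sigma_v^2 / (sigma_a^2 + sigma_v^2))`,
#'   never larger than either unisensory SD).
#' @export
mle_estimate <- function(s_hat_a, s_hat_v, sigma_a, sigma_v) {
  stopifnot(is.finite(s_hat_a), is.finite(s_hat_v))
  w <- mle_weights(sigma_a, sigma_v)
  list(estimate = unname(w["w_a"] * s_hat_a + w["w_v"] * s_hat_v),
       sigma = sqrt(sigma_a^2 * sigma_v^2 / (sigma_a^2 + sigma_v^2)))
}

# normalized Gaussian density over a grid (sums to 1 per mode)
.grid_density <- function(grid, mean, sd) {
  d <- stats::dnorm(grid, mean, sd)
  s <- sum(d)
  if (s <= 0) {
    stop("grid does not cover the estimate (all density mass lost)",
         call. = FALSE)
  }
  d / s
}

# run entry point for the "mle" contract. Static model: one time step.
mle_run_fn <- function(stimuli, params, seed = NULL, grid = NULL, ...) {
  sa <- params[[1L]]  # {mod1}_sigma
  sv <- params[[2L]]  # {mod2}_sigma
  a <- stimuli[[1L]]; v <- stimuli[[2L]]
  if (is.na(sa)) sa <- if (a$noise > 0) a$noise else 3
  if (is.na(sv)) sv <- if (v$noise > 0) v$noise else 3
  if (is.null(grid)) grid <- seq(0, 179, by = 1)
  noiseless <- is.null(seed) || (a$noise == 0 && v$noise == 0)
  s_hat_a <- if (noiseless) a$position else stats::rnorm(1, a$position, sa)
  s_hat_v <- if (noiseless) v$position else stats::rnorm(1, v$position, sv)
  fused <- mle_estimate(s_hat_a, s_hat_v, sa, sv)
  if (s_hat_a < min(grid) || s_hat_a > max(grid) ||
      s_hat_v < min(grid) || s_hat_v > max(grid)) {
    stop("grid does not cover the unisensory estimates", call. = FALSE)
  }
  act <- list(
    auditory = .grid_density(grid, s_hat_a, sa),
    visual = .grid_density(grid, s_hat_v, sv),
    multi = .grid_density(grid, fused$estimate, fused$sigma))
  mode_roles <- c(auditory = "unisensory", visual = "unisensory",
                  multi = "multisensory")
  names(mode_roles) <- c(names(stimuli), "multi")
  names(act) <- names(mode_roles)
  nd_result(act, coords = list(time = 0, x = grid), mode_roles = mode_roles,
            causes = NULL,
            metadata = list(estimates = stats::setNames(
              list(s_hat_a, s_hat_v, fused$estimate, fused$sigma),
              c(names(stimuli), "fused", "fused_sigma"))))
}

.mle_contract <- function(modalities = c("auditory", "visual")) {
  model_contract(
    name = "mle", modalities = modalities,
    param_schema = data.frame(
      name = c("{mod1}_sigma", "{mod2}_sigma"),
      default = c(NA_real_, NA_real_),  # NA = take from stimulus noise, else 3
      lower = c(1e-9, 1e-9), upper = c(Inf, Inf)),
    run = mle_run_fn, dimensions = "space")
}
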