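# Reduced-size networks for fast unit tests: 90 neurons (2 deg/neuron),
# coarser Euler step. Structural properties do not depend on these sizes.
small_av <- function(...) av_net_params(n_neurons = 90L, dt = 0.25, ...)
# the three-layer model keeps full neuron density (its interlayer drive
# scales with neurons per degree) but a coarser step
small_stci <- function(...) stci_params(dt = 0.25, ...)

av_stim <- function(a_pos = 45, v_pos = 51, duration = 150, onset_a = 0,
                    onset_v = 0, int_a = 1, int_v = 1, noise = 0) {
  list(stimulus("auditory", a_pos, onset = onset_a, duration = duration,
                intensity = int_a, noise = noise),
       stimulus("visual", v_pos, onset = onset_v, duration = duration,
                intensity = int_v, noise = noise))
}

final_barycenter <- function(result, mode) {
  a <- get_mode(result, mode)
  barycenter_readout(a[nrow(a), ], result$coords$x)
}

# default BCI parameter set used across tests
bci_p <- function(sigma_a = 1, sigma_v = 1, sigma_p = 1, mu_p = 0,
                  p_common = 0.5) {
  list(sigma_a = sigma_a, sigma_v = sigma_v, sigma_p = sigma_p,
       mu_p = mu_p, p_common = p_common)
}
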