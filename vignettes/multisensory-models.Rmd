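---
title: "Models of multisensory integration and causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of multisensory integration and causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisense)
```

## The problem

When a sound and a light occur close together in space and time, observers
tend to perceive a single audio-visual event and mislocalize the sound
toward the light — the ventriloquist effect. Whether the brain integrates
or segregates the two signals is a causal-inference problem: did they come
from one source or two? Experiments probe this either *implicitly*
(localize the sound under audio-visual disparity; the normalized shift
toward the light is the **auditory bias**) or *explicitly* (judge whether
the two stimuli share a common source; the proportion of "one source"
reports is the **unity judgment**).

`multisense` implements four models of this computation at different
levels of analysis behind one uniform interface, so that any analysis tool
(task protocols, parameter sweeps, Gaussian summaries, fitting) applies to
any model. Every model returns an `nd_result`: a labelled array over
`(mode, time, x, y, z)` with at least two unisensory modes and exactly one
multisensory mode, optional causal-inference output in [0, 1], and run
metadata. Spatial coordinates are degrees, time is milliseconds.

## The models

### Near-optimal bimodal integrator (`mle`)

Reliability-weighted fusion: with unisensory estimates
$\hat S_A, \hat S_V$ and noise SDs $\sigma_A, \sigma_V$,

$$\hat S = w_A \hat S_A + w_V \hat S_V, \qquad
  w_A = \frac{\sigma_V^2}{\sigma_A^2 + \sigma_V^2},\;
  w_V = \frac{\sigma_A^2}{\sigma_A^2 + \sigma_V^2},$$

with fused variance $\sigma_A^2\sigma_V^2 / (\sigma_A^2 + \sigma_V^2)$.
This model always integrates: its auditory bias equals $w_V$ at *every*
disparity, which is exactly why it cannot track behaviour at large
disparities where humans segregate. The model is static (one time step)
and has no unity readout; `run_task()` reports `NA` unity for it unless
the user configures a threshold rule.

### Bayesian causal inference (`bci`)

The generative model draws a source position $s \sim N(\mu_p, \sigma_p)$
(one source under $C=1$, two independent sources under $C=2$) and noisy
measurements $x_m \sim N(s, \sigma_m)$. The likelihoods marginalize over
the sources in closed form; the posterior probability of a common cause is

$$\pi = \frac{p(x_V, x_A \mid C=1)\, p_c}
             {p(x_V, x_A \mid C=1)\, p_c +
              p(x_V, x_A \mid C=2)(1 - p_c)},$$

with $p_c$ = `p_common`. Conditional estimates are precision-weighted
means (both cues plus prior under $C=1$; own cue plus prior under $C=2$),
and the default readout is **model averaging**
$\hat s_A = \pi\,\hat s_{C=1} + (1-\pi)\,\hat s_{A,C=2}$; model selection
and probability matching are also available. All closed forms are tested
against brute-force numerical integration of the generative model
(relative error < 1e-6 over 100 random parameter points).

The same equations run on a temporal axis (onsets in ms) for the temporal
task. Two defaults needed a decision the source material leaves open:
`mu_p` defaults to the *midpoint of the two measurements* in space (this
keeps the posterior symmetric in signed disparity, which the disparity
protocols assume) and to the *visual onset* in time. Both are plain
parameters and can be overridden. For noiseless single presentations the
unity proportion is the posterior itself.

### Two-layer audio-visual rate network (`net_av`)

Two rings of 180 rate neurons (1°/neuron), one auditory and one visual,
with Mexican-hat lateral connectivity
($L_{jk} = L_{ex} e^{-d^2/2\sigma_{ex}^2} - L_{in} e^{-d^2/2\sigma_{in}^2}$,
circular distance, no self-connection) and non-negative Gaussian
cross-modal synapses between rings. Each neuron follows
$\tau \dot z = -z + F(q)$ with sigmoid $F(q) = 1/(1+e^{-s(q-\theta)})$
under Euler integration, and the spatial estimate is the activity
barycenter of a ring. The model has no multisensory layer; its `multi`
mode is the mean of the two layers (a documented surrogate).

**Parameter provenance.** The published appendix with the reference
constants was not available to this implementation, so the defaults are
the package's own, chosen once in the style of this model family and then
frozen: broad fast auditory input (`sigma_stim_a = 32`°, `tau_a = 3` ms)
versus narrow slow visual input (`sigma_stim_v = 4`°, `tau_v = 15` ms),
input gains (`e0` ≈ 32–33) that put a lone stimulus just above the
sigmoid threshold (`slope = 0.4`, `theta = 25`), lateral excitation
`l_ex = 5, sigma_ex = 3`° against wider inhibition `l_in = 4,
sigma_in = 24`°, and cross-modal coupling `w0 = 1.5, sigma_c = 5`°. What
the test suite asserts is *structure*, not these numbers: visual capture
of the auditory barycenter that weakens with disparity (spatial rule),
zero capture when the cross-modal weights are zero, and
inverse effectiveness (proportionally larger multisensory enhancement at
lower intensity, because near-threshold inputs gain most from
convergence).

**Numerical choices.** Fixed-step Euler with `dt = 0.1` ms (`dt` must be
≤ min(τ)/10); trajectories are stored decimated to 1 ms with the final
step always kept. With the inhibition-dominated kernel the bump is
input-driven and decays after stimulus offset, so task protocols sustain
spatial stimuli to the end of the trial and read out the steady state at
the final step. The barycenter is arithmetic over all neurons (valid
because task stimuli sit mid-grid, far from the ring wrap); sub-threshold
activity tails leave a residual pull of ≲ 0.3° toward the grid midpoint,
which is why the decoupled-localization tests use a 0.5° tolerance
rather than exact zero.

### Three-layer spatiotemporal causal-inference network (`net_stci`)

Adds a multisensory layer fed by Gaussian feedforward synapses
(`w0_mc`) from both unisensory rings and feeding back (`w0_cm`) to them,
with its own Mexican-hat kernel (`l_ex_c`, ...) and time constant. Three
temporal mechanisms distinguish it from the two-layer model: pathway
**latencies** (`delta_cm`, `delta_ff`, `delta_fb`; implemented as ring
buffers at `dt` resolution, non-multiples rounding to the nearest step),
first-order low-pass **temporal filters** per population
(`tau_filt_a/v/c`; 0 disables), and the multisensory layer's own
dynamics. The causal readout divides the maximal multisensory rate by
`causes_norm` (default 1, the sigmoid ceiling, making the readout the raw
maximal rate on a natural [0, 1] scale) and the trial-level unity value
is its **peak over time** — a final-time readout would miss transient
multisensory responses under temporal disparity.

The defaults (`w0_mc = 2.0`, `w0_cm = 2.5`) place the multisensory layer
in its sensitive range for the built-in tasks: a lone stimulus drives it
weakly, synchronous co-located audio-visual stimulation drives it
strongly, and the readout falls monotonically with onset disparity over
0–250 ms. This is also what makes the sweep directions come out as the
framework comparison found: multisensory lateral excitation (`l_ex_c`)
and cross-modal weights (`w0_av`) both increase the auditory bias at the
−6° disparity point, mirroring the effect of a higher common-cause prior
in the Bayesian model. With feedforward, feedback, latencies and filters
all off, the unisensory trajectories reduce *bit-exactly* (tolerance
1e-12, same seed) to the two-layer model — the update expressions are
shared term-for-term so the added pathways contribute exact zeros.

## Tasks, metrics and fitting

`default_task()` encodes the three protocols: spatial tasks anchor the
auditory stimulus at 45° with visual disparities ±3, ±6, ±12, ±24°;
the temporal task anchors the visual onset at 160 ms with auditory onset
disparities 0, ±20, ±80, ±150, +250 ms (eight conditions — the design has
no −250 ms condition, which would precede trial start) and co-locates
both stimuli at 90°, the middle of the spatial grid. Each condition runs
once with all noise sources eliminated, so every reported number is
deterministic.

Auditory bias is $(\hat s_A - s_A)/(s_V - s_A)$ — positive means
attraction toward vision on either side; it is undefined at zero
disparity. Unity curves are summarized by a least-squares Gaussian
$P(\Delta) = A e^{-(\Delta-\mu)^2/2w^2}$ with amplitude $A \in [0,1]$,
mean within the disparity span, width in $(0, 2\,\mathrm{span}]$, fitted
by L-BFGS-B from five deterministic starts (best kept); a constant curve
is returned as a flagged degenerate fit rather than an arbitrary width.
`fit_model()` wraps a compact seeded differential-evolution search
(rand/1/bin, population 10 per dimension, F = 0.8, CR = 0.9, bound
truncation) minimizing the SSE between model task outputs and an observed
response table; it recovers a generating `p_common = 0.7` within ±0.05
from a model-generated unity curve in a few hundred evaluations.

Parameter sweeps (`run_sweep`, `cross_sweep`) pre-assign every
(value, repeat) pair a child seed derived from the base seed by a stable
integer hash, so sequential and any parallel execution order give
identical results, and the reduce-on-the-fly strategy provably equals
collect-then-reduce (tested for every model).

## What the deterministic protocols do and do not establish

The built-in tasks emulate the *noiseless single-presentation* design:
one presentation per condition with all noise off. This isolates each
model's systematic behaviour (bias curves, unity curves) but does not
emulate trial-to-trial variability of real observers — proportions from
real experiments are binomial aggregates, while here the Bayesian unity
value *is* the posterior and the network value is a normalized rate. A
green test therefore establishes the model mechanism and its parameter
directions, not a quantitative account of any human dataset; fitting to
real response tables is exactly what `fit_model()` is for, and no human
data ships with the package.

## Known limitations

- The networks are 1-D in space; the result container supports up to
  three spatial axes but no built-in model emits them.
- The two-layer model's `multi` mode is a surrogate (layer mean), so its
  unity readout is coarser than the three-layer model's.
- The arithmetic barycenter is biased near the ring wrap; keep stimuli
  within roughly 20–160°.
- `mu_p` centered between the cues makes the spatial Bayesian prior
  condition-dependent; for a fixed-prior analysis set `mu_p` explicitly.
- Euler integration is first-order: halving `dt` changes trajectories at
  O(dt); all determinism guarantees are at fixed `dt`.
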