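# multisense

Computational models of multisensory integration and causal inference for
the ventriloquist paradigm, behind one uniform interface.

When a sound and a light occur close together, observers often perceive a
single audio-visual event and mislocalize the sound toward the light.
Whether the brain *integrates* or *segregates* the two signals is a causal
inference: one source or two? This package is for computational
neuroscientists and psychophysicists who want to compare models of that
computation across levels of analysis — from normative probabilistic
accounts to neural population dynamics — with the same tasks, metrics,
sweeps and fitting machinery applied to all of them.

## Models

Every model returns the same standardized container (`nd_result`): a
labelled activity array over `(mode, time, x, y, z)` with at least two
unisensory modes and one multisensory mode, an optional causal-inference
readout in [0, 1], and full run metadata. Four models ship built in:

| name | level | core idea |
|---|---|---|
| `mle` | computational | reliability-weighted fusion: ŝ = w_A ŝ_A + w_V ŝ_V with w_A = σ_V²/(σ_A²+σ_V²); always integrates |
| `bci` | computational | Bayesian causal inference: posterior probability π of a common cause from closed-form likelihoods, model-averaged estimates ŝ_A = π ŝ_{C=1} + (1−π) ŝ_{A,C=2} |
| `net_av` | neural | two rings of rate neurons (Mexican-hat lateral kernel, Gaussian cross-modal synapses, sigmoid units, Euler dynamics), barycenter readout |
| `net_stci` | neural | three layers: unisensory rings plus a multisensory layer with feedforward/feedback synapses, pathway latencies and temporal filters; unity = peak normalized multisensory rate |

The task harness implements the three standard protocols: implicit
spatial (auditory bias at visual disparities ±3, ±6, ±12, ±24° around a
45° anchor), explicit spatial (unity judgments at the same disparities),
and explicit temporal (unity judgments at auditory onset disparities 0,
±20, ±80, ±150, +250 ms around a 160 ms visual onset). Unity curves are
summarized by Gaussian fits (amplitude, mean, width) and models can be
fitted to observed response tables with a seeded differential-evolution
search.

## Worked example

```r
library(multisense)

st <- list(stimulus("auditory", position = 45),
           stimulus("visual",   position = 51))
res <- run_model("bci", st, params = list(p_common = 0.5, sigma_a = 8,
                                          sigma_v = 4, sigma_p = 10))
res
#> <nd_result> mode[3] x time[1] x x[180]
#>   modes : auditory(uni), visual(uni), multi(mul)
#>   time  : 1 steps [0, 0] ms
#>   causes: scalar 0.5498
#>   model : bci
```

The sound sits at 45°, the light at 51°. The Bayesian observer reports a
posterior probability of a common cause of 0.550 and an auditory estimate
of 48.05° — pulled 3° toward the light (bias 0.51), because vision is
twice as reliable here. Running the whole implicit-spatial protocol shows
the signature that separates causal inference from forced fusion:

```r
tab <- run_task("bci", default_task("implicit_spatial"),
                params = list(p_common = 0.5, sigma_a = 8, sigma_v = 4,
                              sigma_p = 10))
tab[, c("disparity", "bias", "unity")]
#>   disparity  bias  unity
#>         -24 0.243 0.0834
#>         -12 0.435 0.4208
#>          -6 0.509 0.5498
#>          -3 0.527 0.5817
#>           3 0.527 0.5817
#>           6 0.509 0.5498
#>          12 0.435 0.4208
#>          24 0.243 0.0834

fit_gaussian(tab$disparity, tab$unity)
#> <gaussian_fit> A=0.6121 mu=0.000 w=12.827 (rss 0.00275)
```

Bias *decays* with disparity (0.53 → 0.24) as the observer increasingly
segregates, whereas the `mle` model's bias is flat at
σ_A²/(σ_A²+σ_V²) = 0.8 at every disparity — the mechanism behind its
failure beyond ±6°. The Gaussian summary of the unity curve gives the
amplitude, center and width used to compare models under parameter
sweeps (`run_sweep`, `sweep_metric`).

A command-line wrapper over the same functions lives at
`inst/cli/multisense` (`run`, `task`, `sweep`, `fit` subcommands driven by
a JSON config; results export to HDF5/CSV with a provenance record).

## Acceptance script

`scripts/acceptance.R` re-runs the package's headline computation from
scratch — the three causal-inference protocols across the model families,
the Gaussian summaries of the unity curves, and a seeded sweep over the
common-cause prior — and writes its report to the path given by `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/multisensory-models.Rmd`) documents the
models' assumptions, the default parameters and why they were chosen,
numerical choices, and the limits of what the deterministic protocols
establish.
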