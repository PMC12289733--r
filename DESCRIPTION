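Package: multisense
Title: Computational Models of Multisensory Integration and Causal Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified framework for simulating and comparing computational
    models of multisensory integration in the ventriloquist paradigm. Provides
    a standardized labelled multidimensional result container that makes model
    outputs interoperable across analysis tools, four models spanning Marr's
    levels of analysis (a reliability-weighted maximum-likelihood integrator,
    Bayesian causal inference with model averaging, selection and matching
    readouts, a two-layer audio-visual firing-rate network with Mexican-hat
    lateral connectivity, and a three-layer spatiotemporal causal-inference
    network with feedforward and feedback coupling, input latencies and
    temporal filters), parameter-sweep machinery with interchangeable
    result-processing strategies, and a task harness for implicit (auditory
    bias) and explicit (spatial and temporal unity judgment) causal-inference
    experiments, including Gaussian summaries of unity curves and
    differential-evolution model fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
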