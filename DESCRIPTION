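Package: chimeraNet
Title: Chimera-State Detection and Physics-Informed Seizure Prediction on
    Coupled-Oscillator EEG Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying chimera states (coexisting synchronized and
    desynchronized oscillator communities) in multichannel EEG-like recordings.
    Provides a Kuramoto-Sakaguchi generator of labelled synthetic episodes with
    a three-phase pre-seizure chimera progression; EEG preprocessing
    (polyphase resampling, zero-phase Butterworth bandpass, ICA artifact
    criteria, interictal z-scoring); Hilbert-phase extraction and windowed
    phase-locking-value connectivity; feature-conditioned adjacency refinement
    and 3-clique hypergraph construction; per-cluster Kuramoto order
    parameters, chimera-contrast labelling and three-phase segmentation; a
    hypergraph-convolution + selective state-space network with
    physics-extraction heads trained under Kuramoto-consistency and
    chimera-structure losses; and a seizure-prediction evaluation harness
    (horizon sensitivity, false positives per hour, bootstrap confidence
    intervals, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    deSolve,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'autodiff.R'
    'chimera.R'
    'episode.R'
    'evaluate.R'
    'hypergraph.R'
    'kuramoto.R'
    'losses.R'
    'model.R'
    'phase.R'
    'preprocess.R'
    'train.R'
    'utils.R'
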