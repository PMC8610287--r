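Package: icxfreq
Title: Two-Layer and Compartmental Models of Frequency Integration in the
    Owl's Auditory Space Map
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models of across-frequency synaptic integration in space-specific
    neurons of the barn owl external nucleus of the inferior colliculus (ICx).
    Simulates populations of narrowly frequency-tuned, ITD-tuned input neurons
    (ICcl), builds two-layer neurons whose dendritic subunits apply static
    nonlinearities to Gaussian-weighted input sums before somatic summation
    and a spiking nonlinearity, and quantifies the shape of interaural time
    difference (ITD) tuning curves by half-width and side-peak suppression
    z-scored against published population statistics.  Includes rectified
    linear and sigmoid spiking-nonlinearity fitting with adjusted R-squared
    and leave-one-out cross-validation model selection, a generator of
    synthetic intracellular recordings (tones and tone stacks, median-PSP
    extraction, V_add versus V_stack analysis), and a passive multicompartment
    cable model with AMPA and NMDA synapses driven by Poisson inputs for
    classifying tone-combination integration as linear, quadratic or
    sigmoidal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
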