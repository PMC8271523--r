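Package: pulsereplay
Title: Simulated Record-and-Replay of Radial Pulse Tactile Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A fully software-simulated pipeline for recording and replaying
    radial pulse tactile vibrations. Generates synthetic arterial pulse
    displacement waveforms (percussion wave, tidal wave, dicrotic notch) under
    light, moderate and heavy palpation-force regimes; simulates a PVDF
    rate-sensing recorder and a piezoelectric-bender player with saturation and
    force-dependent damping; decomposes pulse waveforms by empirical mode
    decomposition with a Cauchy-type sifting stop criterion; trains
    per-force-range pointwise inverse models (a linear baseline and a 1-10-1
    back-propagation multilayer perceptron) on intrinsic mode functions; and
    quantifies reproduction fidelity with NRMSE and R-squared, including the
    linear-versus-neural comparison by independent-sample t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tools,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
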