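Package: barrierless
Title: Free-Energy Barriers of Diffusion-Controlled Dissociation and
    Association Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates Gibbs free-energy barriers for electronically
    barrierless (diffusion-controlled) bond dissociation and association
    reactions.  A Morse potential is fitted to relaxed-scan electronic
    energies, the bond-cleavage distance is located from the decay of a
    normalized quantum-chemical bond descriptor, the onset of
    translational and rotational entropy is modelled with a sigmoid
    anchored at half of the total dissociation entropy at the cleavage
    distance, and the sigmoid steepness is lowered iteratively until the
    assembled free-energy curve has no minimum beyond the transition
    state.  Includes a quasi-harmonic rigid-rotor harmonic-oscillator
    entropy engine with low-frequency raising, readers and writers for
    scan tables, descriptor tables and XYZ geometries, a synthetic-case
    generator with analytic barrier oracles, and broom-style tidiers and
    ggplot2 autoplot methods for all fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
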