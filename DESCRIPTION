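Package: sdkr
Title: Deterministic Population-Genetics Simulation of Split-Drive
    Killer-Rescue Gene Drives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, discrete-generation, two-sex genotype-frequency
    engine for threshold-dependent CRISPR gene drives that combine homing with
    toxin-antidote selection.  Implements the split-drive killer-rescue (SDKR)
    system and its extensions: end-joining (NHEJ) resistance alleles, population
    suppression through female-to-male sex conversion or female-specific
    lethality with unidirectional two-deme migration, and the three-locus
    daisy-drive killer-rescue (DDKR) variant.  Experiment drivers compute drive
    trajectories, introduction thresholds by bisection, persistence times,
    equilibrium genetic loads and parameter-grid scans, with a configuration
    layer and command-line interface for reproducible scenario runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
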