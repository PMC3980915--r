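Package: polychron
Title: Rate-to-Temporal Code Conversion in Chaotic Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation of a homogeneous chaotic network of leaky
    integrate-and-fire neurons with distance-dependent conduction delays,
    together with a shift-alignment algorithm that detects polychronous
    neuronal groups (PNGs) in spike rasters and measures their selectivity
    for rate/population-coded stimuli. Includes generators for stimulus and
    noise spike streams, PNG statistics (reaction strength, selectivity,
    pairwise independence), and orchestration of one-factor-at-a-time
    experiment series including an excitatory-delay randomization control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
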