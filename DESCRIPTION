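Package: antagonav
Title: Dual-Detector Pheromone Navigation: Diffusion Fields, Agent Models
    and Sensory-Trace Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how Caenorhabditis elegans males locate a
    volatile sex-pheromone source by antagonistically comparing a
    gradient-sensing head detector with a threshold-sensing tail detector.
    Provides a conservative finite-difference solver for volatile transport
    in a two-layer (air over agar) Petri-dish arena with interpolating
    concentration samplers; a stochastic run-and-tumble agent model whose
    speed and tumble rate are driven by head and tail confidence variables,
    with directed taxis turns and per-detector silencing; trajectory
    analytics (stimulation-locked power spectra, windowed behavioural motif
    classification, chemotaxis indices, cohort success summaries);
    calcium-trace analytics (two-channel ratiometric dR/R0 with
    Savitzky-Golay smoothing, sign-restricted response integrals,
    correlation screening, linear circuit decomposition); an optimal
    turn-angle design analysis for least-squares gradient estimation from
    noisy path samples; and seeded synthetic-data generators for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
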