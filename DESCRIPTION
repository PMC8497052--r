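Package: drycomm
Title: Trait-Structured Vegetation Pattern Formation and Community Assembly in Drylands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a trait-structured reaction-diffusion model of dryland
    plant communities in which many functional groups, arranged along a
    growth versus stress-tolerance tradeoff axis, compete for soil water and
    light while overland water flow and differential infiltration drive
    Turing-type vegetation patterning. Provides the non-spatial (mean-field)
    community assembly solver with trait diffusion (mutation-selection
    equilibria), a stiff 1-D spatial integrator on periodic domains, linear
    stability analysis of single-functional-group states (dispersion
    relations, bare-soil and Turing thresholds, branch tracing by
    time-integration continuation), functional-diversity metrics (richness,
    Shannon index, Pielou evenness), and scenario drivers for community
    emergence, precipitation downshifts, buffering along pattern branches,
    and hybrid uniform/patterned community states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
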