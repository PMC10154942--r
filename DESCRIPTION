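Package: retrofold
Title: Reconstruct Molecular Self-Assembly Energy Trajectories from
    Disassembly Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the energetic asymmetry between molecular
    self-assembly (e.g. protein folding) and disassembly (unfolding).
    Disassembly is typically a fast, constant-rate process while assembly is a
    slow exponential relaxation; a logarithmic rescaling of the time variable
    maps one onto the other.  The package provides closed-form and numerical
    solutions of the underlying damped-oscillator and unstable-potential
    models, readers for delimited time-energy tables and AMBER 'mdout' energy
    logs, a seeded generator of synthetic folding/unfolding energy profiles,
    and a fitting function that reconstructs an approximate folding-energy law
    from an unfolding trajectory and scores it against a reference, following
    the Trp-cage miniprotein case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
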