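Package: pepMFA
Title: Peptide-Based 13C Metabolic Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state 13C metabolic flux analysis from amino-acid or
    peptide mass distribution vectors (MDVs). Parses carbon-transition
    reaction networks, decomposes them into elementary metabolite units
    (EMUs) and simulates isotope labeling for arbitrary flux profiles,
    convolves amino-acid MDVs into peptide MDVs, fits intracellular fluxes
    by weighted nonlinear least squares, computes per-flux confidence
    ranges and the flux information content (FIC) of a measurement set,
    and resolves per-species fluxes in simple microbial communities from
    species-unique peptides. Includes in-silico tryptic digestion, panel
    selection by amino-acid composition, natural-isotope correction
    matrices, and a synthetic-data generator for toy networks and noisy
    measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Biostrings
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
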