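Package: tunnelflex
Title: Flexibility, Interaction and Titration Analysis of Polysaccharide
    Lyase Catalytic Tunnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative structural analysis of pH-series crystal structures
    of tunnel-type polysaccharide lyases. Provides region-wise B-factor
    flexibility profiling with per-structure scaling, enumeration of
    protein-carbohydrate hydrogen bonds and salt bridges with subsite
    assignment, pyranose ring mean-plane fitting and alpha/beta face
    classification, side-chain chi1 rotamer comparison across structures,
    unit-cell and Matthews coefficient metrics, and a desk-scale constant-pH
    Metropolis Monte Carlo titration engine with a pluggable electrostatic
    term. Includes a synthetic-structure generator so that every stage is
    testable from code alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
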