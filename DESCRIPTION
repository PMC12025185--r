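Package: laccmod
Title: Structure-Guided Lysine Modification Analysis and Stability
    Kinetics for Laccases
Version: 0.1.0
Authors@R:
    person("laccmod", "developers", email = "laccmod@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and evaluating chemical modification of
    lysine residues in enzymes, developed around comparative studies of
    bacterial and fungal laccases. Implements atomistic solvent-accessible
    surface area (Shrake-Rupley quadrature), per-residue relative exposure,
    hydrophobic/hydrophilic surface partitioning, Henderson-Hasselbalch
    lysine reactivity scoring from externally predicted pKa values,
    salt-bridge detection, crosslinker distance feasibility, and the
    assay-side statistics: TNBS degree of modification, first-order
    thermal-inactivation kinetics with half-lives and stabilization
    ratios, and pH/temperature activity profile summaries. Includes a
    synthetic-data generator with known ground truth and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
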