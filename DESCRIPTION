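Package: varstruct
Title: Structural Impact Profiling of Missense Protein Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated structural-impact profiling of missense variants on a
    protein structure. Builds rigid-backbone point-mutant models, computes
    wild-type and mutant per-residue structural profiles from first principles
    (Kabsch-Sander secondary structure, Shrake-Rupley solvent accessibility,
    geometric hydrogen bonds, salt bridges, disulfides, hydrophobic contacts),
    diffs them per variant, classifies predicted stability change by a
    3-of-5 predictor consensus, flags evolutionarily conserved positions, maps
    variants onto chemokine-fold regions, and aggregates cohort-level reports.
    Includes deterministic generators of synthetic structures and variant
    cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
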