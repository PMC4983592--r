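Package: seedfate
Title: Seed Removal, Feeding Preference and Endozoochory Analysis for
    Rodent Granivory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for post-dispersal seed fate experiments with
    small rodents. Computes rodent-attributable seed removal rates from paired
    exclosure depots with the Fox zero/exclusion correction, feeding-preference
    scores from cafeteria trials (trapezoidal area under cumulative consumption
    curves, standardized to Rodgers' index), Shannon diversity and Pielou
    evenness of feeding activity, trap-based rodent density, and gut-passage
    seed recovery and germination comparisons. Includes a synthetic-data
    generator that emulates the paired-depot field design and the cafeteria
    observation schedule, and permutation-based trait contrasts with a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
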