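Package: missensemap
Title: Map Population Missense Variants onto Protein Sequences and Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Filters population missense variant tables (gnomAD-style CSV
    exports) to a neutral set, aggregates allele frequencies per residue with
    the disjoint-event addition rule, assigns log10 frequency bins, computes
    per-domain Vd/Vp depletion ratios against whole-protein variant density,
    renders 1D lollipop/domain plots, and emits PyMOL scripts that draw
    frequency-scaled C-alpha spheres on experimental or predicted structures
    (with pLDDT masking). Includes a synthetic-data generator with ground-truth
    sidecars so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
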