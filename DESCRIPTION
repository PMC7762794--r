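Package: htculture
Title: Dilution-to-Extinction Culturing Analysis for Marine Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-throughput dilution-to-extinction
    culturing (HTC) experiments from amplicon sequence variant (ASV) count
    tables. Simulates well-plate inoculation experiments under a Poisson
    extinction model, curates per-culture and environmental ASV counts,
    classifies cultures as monocultures or mixed cultures, estimates percent
    culturability V = -ln(1 - p)/X with exact (Clopper-Pearson) 95%
    confidence limits, maintains an isolate registry, and compares cultured
    ASVs against the source-community profile.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
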