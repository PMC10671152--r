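Package: lssmodr
Title: Mechanistic Gradient Retention Modeling and Design-Space Mapping for
    HPLC Method Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates per-analyte linear-solvent-strength (LSS) retention
    models from a small gradient-time by temperature by ternary-composition
    experimental design, predicts retention times and peak widths at
    arbitrary setpoints (multi-segment gradients, flow changes), maps the
    critical resolution over the design space, extracts the method operable
    design region (MODR), runs in-silico robustness scans, tracks peaks
    across design runs via a mixture-spiking scheme, and computes
    predicted-versus-experimental validation statistics. Includes a fully
    seeded synthetic-data generator so every stage is testable without
    instrument data.
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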