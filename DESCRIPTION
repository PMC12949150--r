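Package: mangroveplan
Title: Climate-Smart Spatial Prioritisation for Mangrove Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing climate-smart protected-area networks for
    mangroves with minimum-set reserve selection. Builds "geomorphic species"
    conservation features (mangrove species subdivided by biophysical
    typology), assigns area-based representation targets by log10
    interpolation of range size, splits each feature into a climate-priority
    area and a remainder using per-unit climate-resilience fields, solves the
    resulting binary minimum-set problem exactly to a stated optimality gap,
    and computes the comparison statistics used to evaluate such plans:
    percent area selected, area-weighted resilience, global versus
    country-scale efficiency, Cohen's kappa agreement between alternative
    prioritisations, threshold sweeps, and protected-area gap audits. A
    seeded synthetic-seascape generator reproduces the statistical structure
    of the global mangrove planning problem at desk scale so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
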