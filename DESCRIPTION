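Package: fameprop
Title: Biodiesel Fuel Properties and Standards Compliance from FAME Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts biodiesel quality properties (cetane number, iodine
    value, long-chain saturated factor and cold filter plugging point) from a
    fatty acid methyl ester (FAME) composition, checks the combined property
    set against the EN 14214 and ASTM D6751 specification limits, and computes
    the culture-performance metrics (specific growth rate, biomass and lipid
    productivity, sedimentation-based medium-removal efficiency) used to rank
    microalgal biodiesel feedstocks. Ships versioned per-ester coefficient
    tables with provenance, a worked microalgal example, and a synthetic-data
    generator for compositional FAME profiles and two-stage growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
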