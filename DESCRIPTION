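Package: rilate
Title: Lateral Thermal Spread Analysis for Bipolar Vessel Sealing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify lateral thermal spread during bipolar vessel
    sealing from thermographic recordings. Extracts the extent of the critical
    zone (tissue heated above 50 degrees Celsius) from calibrated thermal frame
    stacks, relates it to histologically measured necrosis extents, computes
    the RILATE risk index (necrosis extent as a percentage of critical-zone
    extent) with its low/moderate/high classification, and runs the associated
    nonparametric group comparisons (exact and approximate Mann-Whitney U
    tests). Includes a synthetic thermography generator with closed-form ground
    truth for validation, and the complete per-sample reference dataset from a
    published ex vivo porcine carotid sealing study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
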