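Package: segflow
Title: Segmented-Flow Droplet Injection Modelling for Serial Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative framework for aqueous-droplet-in-oil (segmented
    flow) sample injection at pulsed X-ray free-electron lasers. Implements
    the T-junction droplet-generation frequency model with capillary-number
    scaling and weighted prefactor fitting, pulsed-beam train timing and
    duty-cycle accounting, a plug-flow crystal hit-fraction model with jet
    geometry from flow, a Monte Carlo droplet-pulse overlap simulator,
    two-level photodetector trace analysis, detector-panel diffuse-scattering
    profiles, sample-consumption comparison between continuous and segmented
    injection, and synthetic-data generators for all of the above.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
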