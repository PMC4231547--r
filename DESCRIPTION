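Package: careplan
Title: Small-Area Estimation and Confrontation of Demand and Supply for GP Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for local primary-care workforce planning. Estimates the
    demand for general practitioner (GP) care in small areas by synthetic
    estimation: a patient-level regression of annual GP consultation minutes
    on gender, age band, area socioeconomic composition and urbanisation is
    projected onto area census profiles. Estimated demand is then confronted
    with registered GP supply (full-time equivalents) to quantify workload
    per FTE and FTE shortage or surplus, both for each area on its own and
    pooled with its surrounding areas within a distance radius. A synthetic
    data module generates a complete artificial country (geography, census
    profiles, patient registration records and GP supply) so the whole
    pipeline can be exercised and validated without access to restricted
    registration data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
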