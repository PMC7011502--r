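Package: geomaskr
Title: District Assignment and Coverage Estimation for Geomasked Survey Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns geographically masked (geomasked) household-survey
    clusters, such as those released by the Demographic and Health Surveys
    (DHS) program, to second-order administrative districts. Implements three
    assignment methods: Monte-Carlo inversion of the geomask with fractional
    district weights (method A), the modal simulated district (method B), and
    direct point-in-polygon overlay of the released coordinate (method C).
    Downstream, it computes district-level coverage proportions under the
    complex survey design with Taylor linearized variances and logit-scale
    confidence intervals, between-survey change, and agreement between
    estimate sets via Lin's concordance correlation coefficient. A synthetic
    geography and survey generator with known truth supports end-to-end
    validation without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), geosphere, withr, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
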