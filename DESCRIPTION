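Package: twosexlt
Title: Age-Stage, Two-Sex Life Table Analysis for Arthropod Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for age-stage, two-sex life table analysis of
    individual-level arthropod cohort data: age-stage survival and
    fecundity schedules (s_xj, l_x, f_xj, m_x), demographic parameters
    (net reproductive rate, intrinsic rate of increase via bisection of
    the Euler-Lotka equation, finite rate of increase, mean generation
    time), bootstrap standard errors and paired bootstrap tests for
    treatment comparisons, deterministic stage-structured population
    projection from an initial egg pulse, and a synthetic cohort
    generator with presets mimicking published two-spotted spider mite
    cohorts for fully reproducible pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
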