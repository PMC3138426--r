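Package: desr
Title: Dual Endpoint Stopping Rules for Two-Stage Phase II Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and evaluation of single-arm two-stage phase II cancer
    trials with a trinomial endpoint combining tumour response and early
    progressive disease (EPD). Implements the dual endpoint stopping rule
    (DESR), which stops a trial at stage I when responses are few and early
    progressions are many, and declares drug activity after stage II when
    cumulative responses are high or cumulative progressions are low. Provides
    exact operating characteristics (type I error, power, probability of early
    stopping, expected sample size) by enumeration over the trinomial outcome
    lattice, exhaustive threshold search under alpha/power constraints with
    the borderline-value power construction, seedable Monte Carlo verification
    and synthetic cohort generation, the classic Fleming and Gehan single-arm
    designs, and head-to-head comparison of rule sets on observed trial count
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
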