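Package: cartwheel
Title: Consistency Analysis of Cooperative Courtship Displays via Recurrence Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, tracks and quantifies the cooperative cartwheel
    display of lekking manakins. Provides a synthetic scene generator with
    known ground truth, a colour-range quadrant tracker that extracts the
    edge male's vertical-position time series from video frames, recurrence
    quantification analysis (recurrence rate, determinism, laminarity,
    microstate entropy, and a maximum-entropy recurrence radius), display
    metrics (cartwheel flight frequency, female visitation and copulation
    rates), and Gamma log-link mixed models relating display consistency to
    group size and female choice, with parameter-recovery experiments on
    synthetic multi-court datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
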