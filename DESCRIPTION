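Package: pfstep
Title: Cadence-Banded Stepping Biomarkers from Wearable Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating cadence-banded stepping
    biomarkers from event-level accelerometer output. Provides quality
    control of variable-length stepping events (minimum step count,
    cadence range, wear-time validity, recording truncation), cadence-band
    aggregation into the two-integer pfSTEP biomarker (slower-paced and
    faster-paced walking steps per day split at the median walking
    cadence), method-agreement analysis between paired wearable systems
    via a variance-components concordance correlation coefficient with
    cluster-bootstrap intervals, and longitudinal mixed-effects models of
    the association between stepping volume/rate and physical function
    (SPPB score). A synthetic-data module simulates paired-device event
    streams and longitudinal cohorts with known ground truth so the whole
    pipeline is testable without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
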