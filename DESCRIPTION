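Package: actiscore
Title: Count-Scaled Actigraphy Sleep-Wake Scoring and PSG Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores overnight accelerometer activity-count recordings into
    sleep and wake epochs with a count-scaled weighted-sum algorithm anchored
    to bedtime and wake-time flags, and with the Sadeh sleep-index comparator.
    Derives the standard night-level sleep outcomes (onset, offset, sleep
    period time, wake after sleep onset, total sleep time, sleep efficiency)
    and validates device scoring against polysomnography with epoch-by-epoch
    agreement statistics (sensitivity, specificity, accuracy, prevalence- and
    bias-adjusted kappa), Bland-Altman limits of agreement and paired tests.
    Includes a synthetic generator of paired hypnogram and hip/wrist count
    series so the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
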