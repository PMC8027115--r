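Package: hapticnav
Title: Haptic Exploration as Navigation with Merge Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates haptic exploration of discrete cuboid objects by a
    one-finger articulated hand whose only inputs are egocentric slip,
    contact, posture and tactile-landmark signals.  A merge self-organizing
    map (MSOM) learns frequently occurring percept sequences during
    unsupervised exploration; winner/location hit maps turn map activity into
    a posterior over object-centred locations, scored by reconstruction
    accuracy and posterior-weighted geodesic distance.  A two-stage
    actor-critic temporal-difference learner then uses MSOM activity patterns
    as its state to reach goal locations on the object, compared against a
    random-walk-with-memory baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
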