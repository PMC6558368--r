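Package: minimuse
Title: Musical-Abilities Battery Toolkit for Preschool Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing a preschool musical-abilities
    battery: constraint-based stimulus generation for pitch, melody, rhythm and
    tempo oddity tasks (diatonic melody composition, contour-preserving and
    contour-violating single-note mutations, rhythm and tempo variants), audio
    rendering of pure-tone and melodic stimuli with WAV input/output, a
    squared-energy tap-onset detector with refractory suppression and
    synchronization-variability (SEA) scoring, task scoring including a
    phonological-awareness principal-component composite with KMO and Bartlett
    diagnostics, a linear-model analysis ladder (standardized coefficients,
    AIC-based backward elimination, nested-F comparisons, interaction models
    and simple-slopes points), and synthetic cohort, tapping-audio and
    oddity-response generators so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
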