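Package: nutrilight
Title: Personalized Nutrient Profiling on a Traffic-Light Scale with
    Pre/Post Study Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores food recipes against a user's per-meal energy budget
    using a rule-based nutrient-profiling algorithm for type 2 diabetes
    dietary management. Daily energy need is estimated with the
    Harris-Benedict equation; carbohydrate, fat (with a saturated-fat
    check for hypertension), protein, sodium and dietary fiber are
    weighted against recommended ranges and the summed score is rendered
    on an eight-value traffic-light scale. Includes recipe ranking and
    meal planning, scoring of the HPLP nutrition subscale and a nutrition
    self-efficacy composite, paired and two-sample t statistics (pooled
    and Welch) computable from printed summary statistics as well as raw
    data, Levene's test, seeded synthetic recipe and two-group pre/post
    study generators, and Monte-Carlo power estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
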