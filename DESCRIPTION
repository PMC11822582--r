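Package: m2knpm
Title: Health Canada's Marketing-to-Children Nutrient Profile Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies packaged foods and restaurant menu items against
    Health Canada's proposed nutrient profile model for restricting food
    marketing to children (the M2K thresholds for sodium, total sugars and
    saturated plus trans fat). Provides the full pipeline from product
    tables with nutrition declarations and ingredient lists, through
    data cleaning (deduplication, Atwater energy plausibility, missing-data
    exclusion), reference-amount based evaluation bases, ingredient-derived
    exemption flags and per-nutrient threshold verdicts, to brand-level
    portfolio healthfulness summaries. Includes a synthetic branded-food
    data generator with known ground-truth classifications for testing the
    pipeline without proprietary food-composition databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
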