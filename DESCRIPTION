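Package: scalogram
Title: Scalogram Ranking and Mapping of Regional Health-Resource Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks administrative regions by structural health-resource
    endowment using the scalogram technique: per-capita indicator rates are
    scored ordinally from 1 (worst) to 4 (best) indicator by indicator, scores
    are summed within indicator clusters (institutional, human-resource, rural
    institutional) and in total, and regions are classified into five
    development tiers whose class-interval width comes from the Sturges rule.
    Includes delimited-table and schema readers with validation and unit
    normalisation, a synthetic-data generator with a planted development
    gradient for end-to-end testing and parameter-recovery studies, ranked and
    tier-summary report writers, and choropleth-ready GeoJSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
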