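Package: aquarisk
Title: Bottled-Water Contaminant Surveys and Non-Carcinogenic Risk Assessment
Version: 0.1.0
Authors@R: person("Aquarisk", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing bottled-water contaminant surveys with
    left-censored (below detection limit) concentration data: detection
    rates, means over detected values and ranges; compliance checks
    against national (INSO) and WHO drinking-water limits and against
    bottle-label claims; deterministic and Monte-Carlo non-carcinogenic
    risk assessment (chronic daily intake and hazard quotient with
    percentile reporting) for child and adult exposure profiles; rank
    based group comparisons (Mann-Whitney U, Kruskal-Wallis) with tie
    correction and a Kolmogorov-Smirnov normality gate; and a synthetic
    data generator for end-to-end testing. Ships a transcribed two-season
    survey of 30 bottled drinking and mineral water brands (nitrate,
    nitrite and ten elements) as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
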