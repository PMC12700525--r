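Package: odoshift
Title: Range and Emergence-Phenology Shifts from Odonate Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates poleward shifts of species' northern range limits and
    shifts in emergence phenology between two time periods from opportunistic
    occurrence records, as used in cross-continental studies of dragonflies
    and damselflies. Provides equal-area quadrat gridding, a mean-of-k
    northernmost-points range-limit statistic, Weibull extreme-order-statistic
    (optimal linear estimation) onset estimation, randomization null models
    for sampling-intensity bias, an interannual flight-season temperature
    variability metric, trait and range-geography predictor assembly with a
    predictive-power collinearity screen, and frequentist plus Bayesian
    phylogenetic regression with phylogenetic-signal statistics (Pagel's
    lambda, Blomberg's K). A synthetic-data generator with known ground truth
    supports end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
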