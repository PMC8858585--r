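Package: igcv
Title: Confidence Intervals for the Coefficient of Variation of the
    Inverse Gaussian Distribution
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interval estimation for the coefficient of variation (CV) of
    an inverse Gaussian (Wald) distribution, with five constructions: the
    generalized confidence interval (GCI), the adjusted generalized
    confidence interval (AGCI), the bootstrap percentile interval (BPCI),
    the fiducial percentile interval (FCI) and the fiducial
    highest-posterior-density interval (F-HPDCI).  Includes the inverse
    Gaussian density, distribution, quantile and random-generation
    functions, closed-form maximum-likelihood fitting, a Monte Carlo
    engine estimating coverage probability and average length of all
    methods over scenario grids, AIC/BIC model comparison across six
    candidate families, Q-Q diagnostics, and two bundled daily PM2.5
    series from Bangkok monitoring stations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
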