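# igcv

Interval estimation for the **coefficient of variation of an inverse
Gaussian distribution**, aimed at dispersion analysis of positive,
right-skewed environmental series — the motivating use case is daily
PM2.5 concentration data from air-quality monitoring stations.

For $X \sim IG(\mu, \lambda)$, with mean $\mu$ and variance
$\mu^3/\lambda$, the coefficient of variation is
$\theta = \sqrt{\mu/\lambda}$: a unit-free dispersion measure that lets
stations with different mean levels be compared.  Point estimation is
easy ($\hat\mu = \bar X$, $\hat\lambda^{-1} = V = \frac1n \sum_i (X_i^{-1} -
\bar X^{-1})$, $\hat\theta = \sqrt{\hat\mu/\hat\lambda}$); the package is
about *interval* estimation, implementing five constructions built on the
exact sampling facts $\bar X \sim IG(\mu, n\lambda)$ and
$n \lambda V \sim \chi^2_{n-1}$ (independent):

| method | idea |
|---|---|
| GCI | equal-tailed percentiles of the generalized pivot $R_\theta = \sqrt{R_\mu/R_\lambda}$, $R_\lambda = \chi^2_{n-1}/(nV)$, $R_\mu = \bar x / \lvert 1 + Z\sqrt{\bar x/(n R_\lambda)}\rvert$ |
| AGCI | same with a Student-$t$ pivot truncated at zero, $R_{\tilde\mu} = \bar x / \max\{0, 1 + t_{n-1}\sqrt{\bar x V/(n-1)}\}$ |
| BPCI | percentiles of the plug-in CV over bootstrap resamples |
| FCI | equal-tailed percentiles of fiducial draws $\theta = \sqrt{\mu/\lambda}$, $\mu \sim IG(\hat\mu, n\hat\lambda)$, $\lambda \sim (\hat\lambda/n)\chi^2_{n-1}$ |
| F-HPDCI | shortest window containing the nominal mass of the same fiducial draws |

A Monte Carlo engine (`cv_coverage`, `cv_coverage_grid`) estimates
coverage probability and average length of all methods over scenario
grids; `compare_families` screens the distributional assumption by
AIC/BIC against normal, lognormal, Cauchy, exponential and Weibull
alternatives; `qq_points`/`plot` give Q-Q diagnostics.  Two daily PM2.5
series from Bangkok stations (Din Daeng and Bang Khun Thian, January
2021, n = 31 each) ship as fixtures.

## Worked example

```r
library(igcv)
x <- pm25_data("din_daeng")          # 31 daily PM2.5 values (ug/m3)
fit <- ig_fit(x, label = "Din Daeng")
summary(fit)
#> Inverse Gaussian fit: Din Daeng
#>   n = 31,  mean = 53.1229,  shape = 337.9519,  CV = 0.3965
#>   fitted sd = 21.0618,  V = 0.002959
#>   logLik = -134.9682,  AIC = 273.9363,  BIC = 276.8043
#>   data range: [23.5800, 105.7900]

compare_families(x)                  # inverse Gaussian minimizes AIC & BIC
confint(fit, seed = 1)
#> 95% confidence intervals for the inverse Gaussian CV
#>   sample: Din Daeng (n = 31, plug-in CV = 0.3965)
#>  method  lower  upper  length
#>  GCI     0.3190 0.5488 0.2298
#>  AGCI    0.3215 0.5486 0.2271
#>  BPCI    0.2947 0.4705 0.1758
#>  FCI     0.3183 0.5423 0.2239
#>  F-HPDCI 0.3096 0.5291 0.2195
```

The daily PM2.5 level at this station varies with a standard deviation
of roughly 40% of its mean; at n = 31 the pivotal and fiducial 95%
intervals put that dispersion between about 0.31 and 0.55.  The
bootstrap interval is shorter, but the coverage engine shows why that
is not a virtue:

```r
cv_coverage(5, mean = 0.5, shape = 1, reps = 2000,
            settings = mc_settings(profile = "fast"), seed = 11)
#>   n mean shape level  method coverage avg_length ...
#>   5  0.5     1  0.95     GCI   0.9500     2.5134
#>   5  0.5     1  0.95    AGCI   0.9625     2.2795
#>   5  0.5     1  0.95    BPCI   0.5310     0.6301
#>   5  0.5     1  0.95     FCI   0.9640     1.5657
#>   5  0.5     1  0.95 F-HPDCI   0.9445     1.3172
```

At n = 5 the bootstrap percentile interval covers the true CV only ~53%
of the time at nominal 95%, while the pivotal and fiducial methods hold
their level.

A thin command-line wrapper over these functions ships at
`inst/scripts/igcv.R` (subcommands `fit`, `ci`, `simulate`,
`fixtures`).

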