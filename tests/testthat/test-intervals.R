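test_that("order-statistic percentile follows the ceiling convention", {
  expect_equal(percentile(1:100, 0.5), 50)
  expect_equal(percentile(c(3, 1, 2), 0.95), 3)
  expect_equal(percentile(c(1, 2, Inf), 0.99), Inf)
  expect_error(percentile(numeric(0), 0.5), "non-empty")
  expect_error(percentile(1:5, 1), "'q'")
  # type-1 (inverse ECDF) quantile is the same order statistic
  set.seed(4)
  for (i in 1:200) {
    d <- stats::rlnorm(sample(3:60, 1))
    q <- stats::runif(1, 0.01, 0.99)
    expect_identical(percentile(d, q),
                     unname(stats::quantile(d, q, type = 1)))
  }
})

test_that("pivots reduce to the observed value under central auxiliaries", {
  fit <- ig_fit(dd)
  ch <- c(10, 25, 40)
  rl <- gpq_lambda_draws(fit, 3, chisq = ch)
  expect_equal(rl, ch / (fit$n * fit$v), tolerance = 1e-14)
  # Z = 0 makes the mu-pivot equal xbar exactly, so theta^2 * R_lambda = xbar
  th <- gpq_theta_draws(fit, 3, z = rep(0, 3), chisq = ch)
  expect_equal(th^2 * rl, rep(fit$mu, 3), tolerance = 1e-12)
  # t = 0 likewise for the adjusted pivot
  tha <- agci_theta_draws(fit, 3, t = rep(0, 3), chisq = ch)
  expect_equal(as.numeric(tha)^2 * rl, rep(fit$mu, 3), tolerance = 1e-12)
})

test_that("shape pivot has the chi-square location and scale", {
  fit <- ig_fit(rinvgauss(10, 1, 1))  # any valid fit; only n, v matter
  fit$n <- 10L; fit$v <- 0.2
  set.seed(8)
  d <- gpq_lambda_draws(fit, 1e5)
  # E R_lambda = (n-1)/(n v); SE = sqrt(2(n-1))/(n v sqrt(m))
  expect_lt(abs(mean(d) - 4.5), 3 * sqrt(2 * 9) / (10 * 0.2) / sqrt(1e5))
  expect_true(all(d > 0))
  expect_lt(abs(percentile(d, 0.5) - qchisq(0.5, 9) / (10 * 0.2)), 0.05)
})

test_that("adjusted pivot hits infinity at the Student-t tail rate", {
  x <- c(0.1, 5, 0.2, 8, 0.15)  # high-dispersion sample, non-trivial rate
  fit <- ig_fit(x)
  s <- sqrt(fit$mu * fit$v / (fit$n - 1))
  p_inf <- stats::pt(-1 / s, df = fit$n - 1)
  set.seed(21)
  d <- agci_theta_draws(fit, 2e4)
  frac <- mean(is.infinite(d))
  expect_equal(frac, attr(d, "n_inf") / 2e4)
  expect_lt(abs(frac - p_inf), 4 * sqrt(p_inf * (1 - p_inf) / 2e4))
  expect_true(all(d[is.finite(d)] > 0))
})

test_that("an infinite upper bound is flagged, not an error", {
  x <- c(0.01, 10, 0.02)  # so extreme that > alpha/2 of draws are infinite
  fit <- ig_fit(x)
  p_inf <- stats::pt(-1 / sqrt(fit$mu * fit$v / 2), df = 2)
  expect_gt(p_inf, 0.025)
  ci <- ig_cv_ci(fit, methods = "agci",
                 settings = mc_settings(gpq_draws = 2000), seed = 5)
  expect_identical(ci$upper, Inf)
  expect_identical(ci$length, Inf)
  expect_gt(attr(ci, "n_inf"), 0)
})

test_that("fiducial draws have the derived second moment and support", {
  fit <- ig_fit(dd)
  set.seed(31)
  d <- fiducial_cv_draws(fit, draws = 1e5 + 1000, burn_in = 1000)
  expect_length(d, 1e5)
  expect_true(all(is.finite(d) & d > 0))
  # theta^2 = mu/lambda with mu, lambda independent:
  # E[theta^2] = mu_hat * (n/lambda_hat) * E[1/chisq_{n-1}]
  #            = n mu_hat / (lambda_hat (n - 3))
  m2 <- fit$n * fit$mu / (fit$lambda * (fit$n - 3))
  expect_lt(abs(mean(d^2) - m2), 4 * stats::sd(d^2) / sqrt(length(d)))
  # chained recursion: same length contract, deterministic
  set.seed(5)
  c1 <- fiducial_cv_draws(fit, draws = 500, burn_in = 100, chained = TRUE)
  set.seed(5)
  c2 <- fiducial_cv_draws(fit, draws = 500, burn_in = 100, chained = TRUE)
  expect_identical(c1, c2)
  expect_length(c1, 400)
  expect_error(fiducial_cv_draws(fit, draws = 100, burn_in = 100), "burn_in")
})

test_that("bootstrap CV distribution matches exhaustive enumeration at n = 3", {
  x <- c(1, 2, 4)
  ex <- boot3_exhaustive(x)
  fit <- ig_fit(x)
  set.seed(12)
  B <- 4000
  d <- boot_cv_draws(fit, B)
  expect_gte(attr(d, "redraws"), 0)
  # every draw lies on the exhaustive support
  dist <- vapply(d, function(v) min(abs(v - ex$support)), numeric(1))
  expect_lt(max(dist), 1e-10)
  # empirical CDF tracks the exhaustive weights (redraws make the law the
  # conditional-on-non-constant uniform over 24 resamples)
  cdf_th <- cumsum(ex$probs)
  for (j in seq_along(ex$support)) {
    p_emp <- mean(d <= ex$support[j] + 1e-12)
    tol <- 4 * sqrt(cdf_th[j] * (1 - cdf_th[j]) / B) + 1e-12
    expect_lt(abs(p_emp - cdf_th[j]), tol + 1e-9)
  }
  # percentile endpoints are attainable support values
  ci <- percentile_interval(d, 0.95)
  expect_true(all(vapply(ci, function(v) min(abs(v - ex$support)) < 1e-10,
                         logical(1))))
})

test_that("HPD interval equals the brute-force shortest window", {
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  set.seed(13)
  for (i in 1:50) {
    d <- stats::rlnorm(sample(20:300, 1), sdlog = runif(1, 0.2, 1))
    lev <- runif(1, 0.5, 0.99)
    h <- hpd_interval(d, lev)
    expect_equal(h, hpd_oracle(d, lev), tolerance = 1e-14)
    # HPD never longer than the equal-tailed interval on the same draws
    p <- percentile_interval(d, lev)
    expect_lte(diff(h), diff(p))
  }
})

test_that("interval construction is deterministic and stream-stable", {
  a <- ig_cv_ci(dd, seed = 42, settings = mc_settings(profile = "fast"))
  b <- ig_cv_ci(dd, seed = 42, settings = mc_settings(profile = "fast"))
  expect_identical(as.data.frame(a), as.data.frame(b))
  # dropping methods must not perturb the remaining methods' draws
  sub <- ig_cv_ci(dd, methods = c("agci", "fci"), seed = 42,
                  settings = mc_settings(profile = "fast"))
  expect_equal(as.data.frame(sub),
               as.data.frame(a)[a$method %in% c("AGCI", "FCI"), ],
               ignore_attr = TRUE)
})

test_that("percentile intervals nest across confidence levels", {
  fit <- ig_fit(dd)
  set.seed(17)
  d <- gpq_theta_draws(fit, 5000)
  i90 <- percentile_interval(d, 0.90)
  i95 <- percentile_interval(d, 0.95)
  expect_gte(i90[1], i95[1])
  expect_lte(i90[2], i95[2])
  # same property through the top-level interface with a fixed seed
  c90 <- ig_cv_ci(dd, level = 0.90, methods = "gci", seed = 3)
  c95 <- ig_cv_ci(dd, level = 0.95, methods = "gci", seed = 3)
  expect_gte(c90$lower, c95$lower)
  expect_lte(c90$upper, c95$upper)
})

test_that("fiducial HPD and percentile intervals share one draw vector", {
  ci <- ig_cv_ci(dd, methods = c("fci", "fhpd"), seed = 9,
                 settings = mc_settings(fiducial_draws = 5000))
  expect_lte(ci$length[ci$method == "F-HPDCI"],
             ci$length[ci$method == "FCI"])
})

test_that("interval rows are well formed on both bundled stations", {
  for (x in list(dd, bkt)) {
    ci <- ig_cv_ci(x, seed = 1, settings = mc_settings(profile = "fast"))
    expect_equal(nrow(ci), 5)
    expect_true(all(ci$lower > 0))
    expect_true(all(ci$lower < ci$upper))
    expect_equal(ci$length, ci$upper - ci$lower, tolerance = 1e-14)
    expect_equal(ci$level, rep(0.95, 5))
  }
})
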