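#' Monte Carlo settings for the interval constructions
#'
#' Bundles the draw counts used by the stochastic interval methods:
#' \code{gpq_draws} pivotal realizations for the GCI/AGCI methods,
#' \code{bootstrap_draws} resamples for the bootstrap percentile method,
#' and \code{fiducial_draws} fiducial realizations of which the first
#' \code{burn_in} are discarded.  Defaults are the reference study sizes
#' (5000 / 1000 / 20000 with 1000 burn-in); \code{profile = "fast"} gives
#' a reduced profile (2000 / 1000 / 4000 with 1000 burn-in) suitable for
#' large coverage simulations on one CPU.
#'
#' @param gpq_draws number of generalized-pivot realizations.
#' @param bootstrap_draws number of bootstrap resamples.
#' @param fiducial_draws total fiducial realizations (including burn-in).
#' @param burn_in fiducial realizations discarded before summarization;
#'   must be smaller than \code{fiducial_draws}.
#' @param profile \code{"paper"} (default sizes above) or \code{"fast"};
#'   explicit arguments override the profile.
#' @return a list of class \code{"mc_settings"}.
#' @examples
#' mc_settings()
#' mc_settings(profile = "fast")
#' @export
mc_settings <- function(gpq_draws = NULL, bootstrap_draws = NULL,
                        fiducial_draws = NULL, burn_in = NULL,
                        profile = c("paper", "fast")) {
  profile <- match.arg(profile)
  def <- if (profile == "paper")
    list(gpq_draws = 5000L, bootstrap_draws = 1000L,
         fiducial_draws = 20000L, burn_in = 1000L)
  else
    list(gpq_draws = 2000L, bootstrap_draws = 1000L,
         fiducial_draws = 4000L, burn_in = 1000L)
  s <- list(
    gpq_draws = as.integer(gpq_draws %||% def$gpq_draws),
    bootstrap_draws = as.integer(bootstrap_draws %||% def$bootstrap_draws),
    fiducial_draws = as.integer(fiducial_draws %||% def$fiducial_draws),
    burn_in = as.integer(burn_in %||% def$burn_in))
  if (any(vapply(s, function(k) !is.finite(k) || k < 1, logical(1)) &
          c(TRUE, TRUE, TRUE, FALSE)))
    stop("draw counts must be >= 1", call. = FALSE)
  if (s$burn_in < 0 || s$burn_in >= s$fiducial_draws)
    stop("'burn_in' must be in [0, fiducial_draws)", call. = FALSE)
  structure(s, class = "mc_settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mc_settings <- function(x, ...) {
  cat(sprintf(
    "MC settings: %d pivot draws, %d bootstrap resamples, %d fiducial draws (burn-in %d)\n",
    x$gpq_draws, x$bootstrap_draws, x$fiducial_draws, x$burn_in))
  invisible(x)
}

# ---- pivotal / fiducial / bootstrap draw vectors -------------------------

#' Generalized pivotal draws for the inverse Gaussian shape and CV
#'
#' \code{gpq_lambda_draws} realizes the generalized pivotal quantity (GPQ)
#' for the shape parameter,
#' \eqn{R_\lambda = \chi^2_{n-1} / (n V)}, whose observed value is
#' \eqn{\lambda}.  \code{gpq_theta_draws} realizes the CV pivot used by
#' the GCI method: with an independent \eqn{Z \sim N(0,1)},
#' \deqn{R_\mu = \bar x \big/ \left| 1 + Z \sqrt{\bar x / (n R_\lambda)}
#'   \right|, \qquad R_\theta = \sqrt{R_\mu / R_\lambda}.}
#' \code{agci_theta_draws} realizes the adjusted pivot used by the AGCI
#' method, replacing the normal by a Student-t and truncating the
#' denominator at zero: with \eqn{t \sim t_{n-1}},
#' \deqn{R_{\tilde\mu} = \bar x \big/ \max\{0,\; 1 + t \sqrt{\bar x V /
#'   (n-1)}\}, \qquad R_{\tilde\theta} = \sqrt{R_{\tilde\mu} / R_\lambda}.}
#' A zero denominator maps \eqn{R_{\tilde\mu}} (hence
#' \eqn{R_{\tilde\theta}}) to \code{Inf}; infinite draws are retained and
#' sort to the top of the order statistics.  Each adjusted realization
#' shares one chi-square draw between \eqn{R_\lambda} and the CV pivot.
#'
#' The auxiliary variates can be injected through \code{z}, \code{t} and
#' \code{chisq} (mainly for testing the observed-value property: with
#' \code{z = 0} or \code{t = 0} the \eqn{\mu}-pivot equals \eqn{\bar x}
#' exactly); by default they are drawn fresh and independently.
#'
#' @param fit an [ig_fit()] object.
#' @param m number of realizations.
#' @param z,t,chisq optional numeric vectors of length \code{m} replacing
#'   the standard-normal, Student-t and chi-square auxiliary draws.
#' @return numeric vector of \code{m} pivot realizations; for
#'   \code{agci_theta_draws} the number of infinite realizations is
#'   attached as attribute \code{"n_inf"}.
#' @seealso [ig_cv_ci()] which turns these draws into intervals.
#' @export
gpq_lambda_draws <- function(fit, m, chisq = NULL) {
  stopifnot(inherits(fit, "ig_fit"))
  m <- as.integer(m)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  if (is.null(chisq)) chisq <- stats::rchisq(m, df = fit$n - 1)
  chisq / (fit$n * fit$v)
}

#' @rdname gpq_lambda_draws
#' @export
gpq_theta_draws <- function(fit, m, z = NULL, chisq = NULL) {
  stopifnot(inherits(fit, "ig_fit"))
  m <- as.integer(m)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  r_lambda <- gpq_lambda_draws(fit, m, chisq = chisq)
  if (is.null(z)) z <- stats::rnorm(m)
  r_mu <- fit$mu / abs(1 + z * sqrt(fit$mu / (fit$n * r_lambda)))
  sqrt(r_mu / r_lambda)
}

#' @rdname gpq_lambda_draws
#' @export
agci_theta_draws <- function(fit, m, t = NULL, chisq = NULL) {
  stopifnot(inherits(fit, "ig_fit"))
  m <- as.integer(m)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  r_lambda <- gpq_lambda_draws(fit, m, chisq = chisq)
  if (is.null(t)) t <- stats::rt(m, df = fit$n - 1)
  den <- pmax(0, 1 + t * sqrt(fit$mu * fit$v / (fit$n - 1)))
  r_mu <- ifelse(den > 0, fit$mu / den, Inf)
  structure(sqrt(r_mu / r_lambda), n_inf = sum(den == 0))
}

#' Bootstrap draws of the plug-in CV
#'
#' Resamples the data with replacement \code{B} times and recomputes the
#' inverse Gaussian plug-in CV \eqn{\hat\theta^* = \sqrt{\bar x^* V^*}} of
#' each resample.  A degenerate resample (all values equal, for which the
#' CV MLE does not exist) is redrawn; the redraw count is attached as
#' attribute \code{"redraws"}.
#'
#' @param fit an [ig_fit()] object carrying the original data.
#' @param B number of bootstrap resamples.
#' @return numeric vector of \code{B} bootstrap CV replicates.
#' @export
boot_cv_draws <- function(fit, B) {
  stopifnot(inherits(fit, "ig_fit"))
  B <- as.integer(B)
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  x <- fit$data
  n <- fit$n
  X <- matrix(sample(x, n * B, replace = TRUE), nrow = B, ncol = n)
  redraws <- 0L
  repeat {
    bad <- which(.row_constant(X))
    if (!length(bad)) break
    redraws <- redraws + length(bad)
    X[bad, ] <- sample(x, n * length(bad), replace = TRUE)
  }
  rm <- rowMeans(X)
  v <- rowMeans(1 / X) - 1 / rm
  structure(sqrt(rm * v), redraws = redraws)
}

# constant-row indicator without external dependencies
.row_constant <- function(X) {
  rowSums(X == X[, 1L]) == ncol(X)
}

#' Fiducial draws of the inverse Gaussian CV
#'
#' Samples the fiducial distribution of \eqn{\theta = \sqrt{\mu/\lambda}}
#' obtained by plugging the MLEs into the sampling distributions of
#' \eqn{(\bar X, V)}:
#' \deqn{\mu \sim IG(\hat\mu,\, n \hat\lambda), \qquad
#'   \lambda \sim (\hat\lambda / n)\, \chi^2_{n-1},}
#' with \eqn{\theta^{(t)} = \sqrt{\mu^{(t)} / \lambda^{(t)}}}.  By default
#' the draws are i.i.d. from these fixed-MLE fiducial distributions, which
#' samples the target exactly; the first \code{burn_in} draws are still
#' discarded so draw counts match an MCMC-style run.  With
#' \code{chained = TRUE} each draw instead plugs in the previous
#' realization (a Gibbs-style recursion) — provided for comparison, where
#' the burn-in is doing real work.
#'
#' @param fit an [ig_fit()] object.
#' @param draws total number of realizations before burn-in.
#' @param burn_in number of initial realizations discarded.
#' @param chained logical; use the chained recursion instead of i.i.d.
#'   fixed-MLE sampling.
#' @return numeric vector of \code{draws - burn_in} positive CV
#'   realizations.
#' @seealso [ig_cv_ci()]; the FCI method takes equal-tailed percentiles of
#'   these draws and the F-HPDCI method the shortest window
#'   ([hpd_interval()]).
#' @export
fiducial_cv_draws <- function(fit, draws = 20000, burn_in = 1000,
                              chained = FALSE) {
  stopifnot(inherits(fit, "ig_fit"))
  draws <- as.integer(draws); burn_in <- as.integer(burn_in)
  if (draws < 1) stop("'draws' must be >= 1", call. = FALSE)
  if (burn_in < 0 || burn_in >= draws)
    stop("'burn_in' must be in [0, draws)", call. = FALSE)
  n <- fit$n
  if (!chained) {
    mu_t <- rinvgauss(draws, fit$mu, n * fit$lambda)
    lambda_t <- fit$lambda / n * stats::rchisq(draws, df = n - 1)
  } else {
    mu_t <- lambda_t <- numeric(draws)
    mu_c <- fit$mu; lam_c <- fit$lambda
    for (i in seq_len(draws)) {
      mu_t[i] <- rinvgauss(1, mu_c, n * lam_c)
      lambda_t[i] <- lam_c / n * stats::rchisq(1, df = n - 1)
      mu_c <- mu_t[i]; lam_c <- lambda_t[i]
    }
  }
  theta <- sqrt(mu_t / lambda_t)
  if (burn_in > 0) theta <- theta[-seq_len(burn_in)]
  theta
}

# ---- percentile and HPD summaries ----------------------------------------

#' Order-statistic percentile of a draw vector
#'
#' Returns the \eqn{\lceil q m \rceil}-th order statistic of the ascending
#' sort of \code{draws} (\code{Inf} sorts last).  This is the percentile
#' convention used by every equal-tailed interval in the package.
#'
#' @param draws non-empty numeric vector (\code{Inf} allowed).
#' @param q probability in (0, 1).
#' @export
percentile <- function(draws, q) {
  if (!length(draws)) stop("'draws' must be non-empty", call. = FALSE)
  if (length(q) != 1 || !is.finite(q) || q <= 0 || q >= 1)
    stop("'q' must lie strictly in (0, 1)", call. = FALSE)
  sort(draws)[ceiling(q * length(draws))]
}

#' Equal-tailed and highest-density interval summaries of draws
#'
#' \code{percentile_interval} is the equal-tailed interval
#' \eqn{[Q(\alpha/2), Q(1 - \alpha/2)]} using the order-statistic
#' convention of [percentile()].  \code{hpd_interval} is the shortest
#' contiguous interval containing \eqn{\lceil (1-\alpha) m \rceil} sorted
#' draws, found by a sliding-window scan; ties are broken by the earliest
#' window.  On the same draw vector the HPD interval is never longer than
#' the equal-tailed one.
#'
#' @param draws non-empty numeric vector.
#' @param level nominal coverage \eqn{1 - \alpha} in (0, 1).
#' @return numeric vector \code{c(lower, upper)}.
#' @export
percentile_interval <- function(draws, level = 0.95) {
  .check_level(level)
  alpha <- 1 - level
  c(percentile(draws, alpha / 2), percentile(draws, 1 - alpha / 2))
}

#' @rdname percentile_interval
#' @export
hpd_interval <- function(draws, level = 0.95) {
  .check_level(level)
  if (!length(draws)) stop("'draws' must be non-empty", call. = FALSE)
  s <- sort(draws)
  m <- length(s)
  k <- ceiling(level * m)
  if (k >= m) return(c(s[1], s[m]))
  width <- s[k:m] - s[1:(m - k + 1)]
  j <- which.min(width)  # which.min takes the first minimum: earliest window
  c(s[j], s[j + k - 1])
}

.check_level <- function(level) {
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1)
    stop("'level' must lie strictly in (0, 1)", call. = FALSE)
}

# ---- the five interval methods -------------------------------------------

.cv_methods <- c("gci", "agci", "bpci", "fci", "fhpd")
.method_labels <- c(gci = "GCI", agci = "AGCI", bpci = "BPCI",
                    fci = "FCI", fhpd = "F-HPDCI")

#' Confidence intervals for the CV of an inverse Gaussian distribution
#'
#' Computes two-sided confidence intervals for the coefficient of
#' variation \eqn{\theta = \sqrt{\mu/\lambda}} by up to five
#' constructions:
#' \describe{
#'   \item{\code{"gci"}}{generalized confidence interval — equal-tailed
#'     percentiles of the generalized pivot \eqn{R_\theta}
#'     ([gpq_theta_draws()]);}
#'   \item{\code{"agci"}}{adjusted GCI — percentiles of the Student-t
#'     adjusted pivot \eqn{R_{\tilde\theta}} ([agci_theta_draws()]); a
#'     truncated-to-zero denominator yields \code{Inf} draws, and if more
#'     than \eqn{\alpha/2} of the draws are infinite the upper bound is
#'     \code{Inf} (flagged, not an error);}
#'   \item{\code{"bpci"}}{bootstrap percentile interval — percentiles of
#'     the plug-in CV over resamples ([boot_cv_draws()]);}
#'   \item{\code{"fci"}}{fiducial interval — equal-tailed percentiles of
#'     the fiducial CV draws ([fiducial_cv_draws()]);}
#'   \item{\code{"fhpd"}}{fiducial highest-posterior-density interval —
#'     the shortest window containing the nominal mass of the same
#'     fiducial draws ([hpd_interval()]).}
#' }
#' \code{"fci"} and \code{"fhpd"} consume one shared fiducial draw
#' vector.  Each method receives its own deterministic sub-seed derived
#' from \code{seed}, so restricting \code{methods} does not change the
#' draws any remaining method sees.
#'
#' @param x numeric vector of positive observations, or an [ig_fit()].
#' @param level nominal coverage in (0, 1); default 0.95.
#' @param methods subset of \code{c("gci", "agci", "bpci", "fci",
#'   "fhpd")}.
#' @param settings an [mc_settings()] object with the draw counts.
#' @param seed optional integer root seed for reproducibility.
#' @param chained logical, passed to [fiducial_cv_draws()].
#' @return a data frame of class \code{"ig_cv_ci"} with one row per
#'   method and columns \code{method}, \code{level}, \code{lower},
#'   \code{upper}, \code{length}, plus attributes \code{cv_hat},
#'   \code{n}, \code{n_inf} (infinite AGCI draws) and \code{redraws}
#'   (degenerate bootstrap resamples redrawn).
#' @examples
#' x <- pm25_data("din_daeng")
#' ig_cv_ci(x, seed = 1)
#' @export
ig_cv_ci <- function(x, level = 0.95, methods = .cv_methods,
                     settings = mc_settings(), seed = NULL,
                     chained = FALSE) {
  fit <- if (inherits(x, "ig_fit")) x else ig_fit(x, label = "sample")
  .check_level(level)
  methods <- match.arg(methods, .cv_methods, several.ok = TRUE)
  stopifnot(inherits(settings, "mc_settings"))
  if (!is.null(seed)) set.seed(seed)
  # one sub-seed per draw source, in fixed canonical order, so that
  # dropping a method never perturbs another method's stream
  sub <- sample.int(.Machine$integer.max - 1L, 4L)
  names(sub) <- c("gci", "agci", "bpci", "fiducial")

  n_inf <- 0L; redraws <- 0L
  fid <- NULL
  need_fid <- any(c("fci", "fhpd") %in% methods)
  if (need_fid) {
    set.seed(sub[["fiducial"]])
    fid <- fiducial_cv_draws(fit, settings$fiducial_draws,
                             settings$burn_in, chained = chained)
  }
  rows <- lapply(methods, function(meth) {
    ci <- switch(meth,
      gci = {
        set.seed(sub[["gci"]])
        percentile_interval(gpq_theta_draws(fit, settings$gpq_draws), level)
      },
      agci = {
        set.seed(sub[["agci"]])
        d <- agci_theta_draws(fit, settings$gpq_draws)
        n_inf <<- attr(d, "n_inf")
        percentile_interval(d, level)
      },
      bpci = {
        set.seed(sub[["bpci"]])
        d <- boot_cv_draws(fit, settings$bootstrap_draws)
        redraws <<- attr(d, "redraws")
        percentile_interval(d, level)
      },
      fci = percentile_interval(fid, level),
      fhpd = hpd_interval(fid, level))
    data.frame(method = .method_labels[[meth]], level = level,
               lower = ci[1], upper = ci[2], length = ci[2] - ci[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ig_cv_ci", "data.frame"),
            cv_hat = fit$cv, n = fit$n, label = fit$label,
            n_inf = n_inf, redraws = redraws, seed = seed)
}

#' @export
print.ig_cv_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%d%% confidence intervals for the inverse Gaussian CV\n",
              round(100 * x$level[1])))
  cat(sprintf("  sample: %s (n = %d, plug-in CV = %.*f)\n",
              attr(x, "label"), attr(x, "n"), digits, attr(x, "cv_hat")))
  tab <- data.frame(method = format(x$method),
                    lower = sprintf("%.*f", digits, x$lower),
                    upper = sprintf("%.*f", digits, x$upper),
                    length = sprintf("%.*f", digits, x$length))
  print(tab, row.names = FALSE, right = FALSE)
  if (attr(x, "n_inf") > 0)
    cat(sprintf("  note: %d infinite adjusted-pivot draw(s)\n", attr(x, "n_inf")))
  invisible(x)
}

#' Confidence interval method for inverse Gaussian fits
#'
#' \code{confint} on an [ig_fit()] delegates to [ig_cv_ci()]: the
#' parameter of interest is the coefficient of variation.
#'
#' @param object an [ig_fit()] object.
#' @param parm only \code{"cv"} is supported.
#' @param level nominal coverage.
#' @param ... passed on to [ig_cv_ci()] (\code{methods}, \code{settings},
#'   \code{seed}).
#' @export
confint.ig_fit <- function(object, parm = "cv", level = 0.95, ...) {
  if (!identical(parm, "cv"))
    stop("only 'cv' intervals are implemented", call. = FALSE)
  ig_cv_ci(object, level = level, ...)
}
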