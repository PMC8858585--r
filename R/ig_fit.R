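#' Fit an inverse Gaussian distribution by maximum likelihood
#'
#' Closed-form maximum-likelihood estimation for a single positive-valued
#' sample \eqn{X_1, \ldots, X_n} assumed to follow an inverse Gaussian
#' distribution \eqn{IG(\mu, \lambda)}.  The MLEs are
#' \deqn{\hat\mu = \bar X, \qquad
#'   \hat\lambda^{-1} = V = \frac{1}{n} \sum_{i=1}^n
#'   \left( X_i^{-1} - \bar X^{-1} \right),}
#' and the plug-in coefficient of variation is
#' \eqn{\hat\theta = \sqrt{\hat\mu/\hat\lambda}}.  The pair
#' \eqn{(\bar X, V)} is complete and sufficient, with \eqn{\bar X \sim
#' IG(\mu, n\lambda)} and \eqn{n \lambda V \sim \chi^2_{n-1}}
#' independently; these sampling distributions drive the pivotal and
#' fiducial interval constructions in [ig_cv_ci()].
#'
#' The divisor in \eqn{V} is \eqn{n} (the ML convention), not
#' \eqn{n - 1}.
#'
#' @param x numeric vector of positive observations, \eqn{n \ge 2}, not
#'   all equal (a constant sample has \eqn{V = 0} and an infinite
#'   \eqn{\hat\lambda}, and is rejected).
#' @param label optional provenance label stored with the fit.
#' @return an object of class \code{"ig_fit"}: a list with components
#'   \item{mu}{\eqn{\hat\mu}, the sample mean;}
#'   \item{lambda}{\eqn{\hat\lambda = 1/V};}
#'   \item{v}{the statistic \eqn{V};}
#'   \item{cv}{\eqn{\hat\theta = \sqrt{\hat\mu/\hat\lambda}};}
#'   \item{n}{the sample size;}
#'   \item{data}{the data vector;}
#'   \item{label}{the provenance label.}
#' @seealso [confint.ig_fit()] for interval estimation of the CV,
#'   [compare_families()] for AIC/BIC comparison against other families,
#'   [plot.ig_fit()] for a Q-Q diagnostic.
#' @examples
#' x <- pm25_data("din_daeng")
#' fit <- ig_fit(x)
#' fit
#' coef(fit)
#' AIC(fit)
#' @export
ig_fit <- function(x, label = deparse(substitute(x))) {
  label <- as.character(label)[1]
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("'x' contains non-finite values", call. = FALSE)
  if (any(x <= 0)) stop("'x' must be strictly positive", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  mu <- base::mean(x)
  v <- base::mean(1 / x) - 1 / mu
  if (v <= 0)
    stop("degenerate sample: all observations equal (V = 0, infinite shape MLE)",
         call. = FALSE)
  structure(
    list(mu = mu, lambda = 1 / v, v = v, cv = sqrt(mu * v), n = n,
         data = x, label = label),
    class = "ig_fit")
}

#' @export
print.ig_fit <- function(x, digits = 4, ...) {
  cat("Inverse Gaussian fit:", x$label, "\n")
  cat(sprintf("  n = %d,  mean = %.*f,  shape = %.*f,  CV = %.*f\n",
              x$n, digits, x$mu, digits, x$lambda, digits, x$cv))
  invisible(x)
}

#' @export
coef.ig_fit <- function(object, ...) {
  c(mean = object$mu, shape = object$lambda)
}

#' @export
logLik.ig_fit <- function(object, ...) {
  ll <- sum(dinvgauss(object$data, object$mu, object$lambda, log = TRUE))
  structure(ll, df = 2, nobs = object$n, class = "logLik")
}

#' @export
summary.ig_fit <- function(object, ...) {
  ll <- logLik(object)
  structure(
    list(fit = object, loglik = as.numeric(ll),
         aic = stats::AIC(object), bic = stats::BIC(object),
         range = range(object$data), sd = sqrt(object$mu^3 / object$lambda)),
    class = "summary.ig_fit")
}

#' @export
print.summary.ig_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  fitted sd = %.*f,  V = %.*g\n", digits, x$sd, 6, x$fit$v))
  cat(sprintf("  logLik = %.*f,  AIC = %.*f,  BIC = %.*f\n",
              digits, x$loglik, digits, x$aic, digits, x$bic))
  cat(sprintf("  data range: [%.*f, %.*f]\n",
              digits, x$range[1], digits, x$range[2]))
  invisible(x)
}

#' Simulate from a fitted inverse Gaussian model
#'
#' Draws samples of the original size from \eqn{IG(\hat\mu, \hat\lambda)}.
#'
#' @param object an [ig_fit()] object.
#' @param nsim number of simulated samples.
#' @param seed optional integer seed; set before drawing.
#' @param ... unused.
#' @return a data frame with \code{object$n} rows and \code{nsim} columns.
#' @export
simulate.ig_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(
    matrix(rinvgauss(object$n * nsim, object$mu, object$lambda),
           nrow = object$n, ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Quantile residuals of an inverse Gaussian fit
#'
#' Randomized-free quantile residuals
#' \eqn{\Phi^{-1}\{F(x_i; \hat\mu, \hat\lambda)\}}; approximately standard
#' normal when the model is adequate.
#'
#' @param object an [ig_fit()] object.
#' @param ... unused.
#' @export
residuals.ig_fit <- function(object, ...) {
  stats::qnorm(pinvgauss(object$data, object$mu, object$lambda))
}

#' Q-Q points for an inverse Gaussian fit
#'
#' Pairs the fitted theoretical quantile at probability \eqn{(i - 0.5)/n}
#' with the \eqn{i}-th order statistic of the data, the standard plotting
#' positions for a distributional Q-Q plot.
#'
#' @param x numeric data vector, or an [ig_fit()] object.
#' @param fit optionally, an [ig_fit()] supplying \eqn{(\hat\mu,
#'   \hat\lambda)}; defaults to fitting \code{x}.
#' @return a data frame with columns \code{theoretical} (strictly
#'   increasing fitted quantiles) and \code{empirical} (sorted data).
#' @examples
#' head(qq_points(pm25_data("din_daeng")))
#' @export
qq_points <- function(x, fit = NULL) {
  if (inherits(x, "ig_fit")) { fit <- x; x <- fit$data }
  if (is.null(fit)) fit <- ig_fit(x, label = "qq")
  n <- length(x)
  p <- (seq_len(n) - 0.5) / n
  data.frame(theoretical = qinvgauss(p, fit$mu, fit$lambda),
             empirical = sort(x))
}

#' Q-Q plot method for inverse Gaussian fits
#'
#' @param x an [ig_fit()] object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.ig_fit <- function(x, ...) {
  qq <- qq_points(x$data, x)
  graphics::plot(qq$theoretical, qq$empirical,
                 xlab = "Theoretical quantiles", ylab = "Sample quantiles",
                 main = paste("Inverse Gaussian Q-Q plot:", x$label), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(qq)
}
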