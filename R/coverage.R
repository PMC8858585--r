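#' Coverage probability and average length of the CV interval methods
#'
#' Monte Carlo estimation of the empirical coverage probability
#' \eqn{CP = c(L \le \theta \le U)/M} and average length
#' \eqn{AL = \sum (U - L)/M} of the interval constructions in
#' [ig_cv_ci()], for one scenario \eqn{(n, \mu, \lambda)} with true CV
#' \eqn{\theta = \sqrt{\mu/\lambda}}.  Each of the \code{reps}
#' replications draws a fresh sample from \eqn{IG(\mu, \lambda)}, builds
#' the requested intervals, and scores the closed-interval indicator
#' \eqn{L \le \theta \le U}.
#'
#' Replications are given independent pre-drawn sub-seeds, so the result
#' is reproducible under any execution order and a grid run equals the
#' corresponding single runs.  An adjusted-pivot (AGCI) replication whose
#' upper bound is infinite counts as covering iff \eqn{\theta \ge L}; it
#' is excluded from the average length and reported in
#' \code{inf_upper}.
#'
#' @param n sample size per replication (\eqn{\ge 2}).
#' @param mean,shape true inverse Gaussian parameters \eqn{\mu, \lambda}.
#' @param level nominal coverage; default 0.95.
#' @param reps number of outer replications \eqn{M}.
#' @param methods subset of \code{c("gci", "agci", "bpci", "fci",
#'   "fhpd")}.
#' @param settings an [mc_settings()] object; the default \code{"fast"}
#'   profile keeps a 2000-replication scenario in the seconds-to-minutes
#'   range on one CPU.
#' @param seed optional integer root seed.
#' @return a data frame of class \code{"cv_coverage"} with one row per
#'   method: columns \code{n}, \code{mean}, \code{shape}, \code{level},
#'   \code{method}, \code{coverage}, \code{avg_length}, \code{reps},
#'   \code{inf_upper}, \code{failures}.
#' @examples
#' cv_coverage(10, mean = 1, shape = 2, reps = 20,
#'             methods = "gci",
#'             settings = mc_settings(gpq_draws = 500), seed = 1)
#' @export
cv_coverage <- function(n, mean, shape, level = 0.95, reps = 1000,
                        methods = .cv_methods,
                        settings = mc_settings(profile = "fast"),
                        seed = NULL) {
  n <- as.integer(n)
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  .check_ig_params(mean, shape)
  .check_level(level)
  reps <- as.integer(reps)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  methods <- match.arg(methods, .cv_methods, several.ok = TRUE)
  stopifnot(inherits(settings, "mc_settings"))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)

  theta <- sqrt(mean / shape)
  alpha <- 1 - level
  nm <- length(methods)
  cover <- len_sum <- len_n <- inf_upper <- failures <- numeric(nm)
  names(cover) <- methods

  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    x <- rinvgauss(n, mean, shape)
    fit <- tryCatch(ig_fit(x, label = "sim"), error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1; next }
    ci_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    ci <- tryCatch(
      ig_cv_ci(fit, level = level, methods = methods,
               settings = settings, seed = ci_seed),
      error = function(e) NULL)
    if (is.null(ci)) { failures <- failures + 1; next }
    for (j in seq_len(nm)) {
      L <- ci$lower[j]; U <- ci$upper[j]
      if (is.infinite(U)) {
        inf_upper[j] <- inf_upper[j] + 1
        if (theta >= L) cover[j] <- cover[j] + 1
      } else {
        if (theta >= L && theta <= U) cover[j] <- cover[j] + 1
        len_sum[j] <- len_sum[j] + (U - L)
        len_n[j] <- len_n[j] + 1
      }
    }
  }
  out <- data.frame(
    n = n, mean = mean, shape = shape, level = level,
    method = .method_labels[methods],
    coverage = cover / reps,
    avg_length = ifelse(len_n > 0, len_sum / len_n, NA_real_),
    reps = reps, inf_upper = as.integer(inf_upper),
    failures = as.integer(failures))
  rownames(out) <- NULL
  structure(out, class = c("cv_coverage", "data.frame"), seed = seed)
}

#' Run a grid of coverage scenarios
#'
#' Applies [cv_coverage()] to each row of a scenario data frame, with
#' deterministic per-scenario sub-seeds derived from one root seed, and
#' binds the results in input order.
#'
#' @param scenarios data frame with columns \code{n}, \code{mean},
#'   \code{shape} and optionally \code{level} and \code{reps}.
#' @param level,reps,methods,settings defaults applied to scenarios that
#'   do not carry their own; see [cv_coverage()].
#' @param seed optional integer root seed.
#' @return a \code{"cv_coverage"} data frame with all scenarios stacked.
#' @examples
#' grid <- expand.grid(n = c(5, 10), mean = 0.5, shape = c(1, 2))
#' cv_coverage_grid(grid, reps = 10, methods = "fci",
#'                  settings = mc_settings(fiducial_draws = 2000),
#'                  seed = 1)
#' @export
cv_coverage_grid <- function(scenarios, level = 0.95, reps = 1000,
                             methods = .cv_methods,
                             settings = mc_settings(profile = "fast"),
                             seed = NULL) {
  if (!is.data.frame(scenarios) || nrow(scenarios) == 0)
    stop("'scenarios' must be a non-empty data frame", call. = FALSE)
  need <- c("n", "mean", "shape")
  if (!all(need %in% names(scenarios)))
    stop("'scenarios' needs columns n, mean, shape", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sc_seeds <- sample.int(.Machine$integer.max - 1L, nrow(scenarios))
  res <- lapply(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, ]
    cv_coverage(row$n, row$mean, row$shape,
                level = row$level %||% level,
                reps = row$reps %||% reps,
                methods = methods, settings = settings,
                seed = sc_seeds[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("cv_coverage", "data.frame"), seed = seed)
}

#' @export
print.cv_coverage <- function(x, digits = 4, ...) {
  cat("Monte Carlo coverage of CV interval methods\n")
  df <- as.data.frame(x)
  df$coverage <- round(df$coverage, digits)
  df$avg_length <- round(df$avg_length, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
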