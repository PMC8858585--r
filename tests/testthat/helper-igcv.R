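# shared fixtures and independent oracles

dd <- pm25_data("din_daeng")
bkt <- pm25_data("bang_khun_thian")

# brute-force shortest-window oracle for HPD intervals
hpd_oracle <- function(draws, level) {
  s <- sort(draws)
  m <- length(s)
  k <- ceiling(level * m)
  best <- c(s[1], s[m])
  if (k >= m) return(best)
  best_len <- Inf
  for (j in 1:(m - k + 1)) {
    len <- s[j + k - 1] - s[j]
    if (len < best_len - 0) {          # strict: earliest window wins ties
      best_len <- len
      best <- c(s[j], s[j + k - 1])
    }
  }
  best
}

# exhaustive bootstrap distribution of the plug-in CV for n = 3,
# conditional on non-constant resamples (degenerate ones are redrawn)
boot3_exhaustive <- function(x) {
  stopifnot(length(x) == 3)
  idx <- expand.grid(1:3, 1:3, 1:3)
  cvs <- apply(idx, 1, function(i) {
    xs <- x[unlist(i)]
    if (length(unique(xs)) == 1) return(NA_real_)
    m <- mean(xs)
    sqrt(m * (mean(1 / xs) - 1 / m))
  })
  cvs <- cvs[!is.na(cvs)]
  support <- sort(unique(round(cvs, 12)))
  probs <- vapply(support, function(s) mean(abs(cvs - s) < 1e-9), numeric(1))
  list(support = support, probs = probs)
}
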