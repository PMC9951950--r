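# Independent, loop-based evaluation of every agreement descriptor, written
# straight from the definitions. Deliberately slow and scalar so it shares
# no code path with the package implementation.

oracle_metrics <- function(o, s) {
  n <- length(o)
  mean_o <- 0; mean_s <- 0
  for (i in 1:n) { mean_o <- mean_o + o[i] / n; mean_s <- mean_s + s[i] / n }
  var_o <- 0; var_s <- 0; cov_os <- 0
  for (i in 1:n) {
    var_o <- var_o + (o[i] - mean_o)^2 / n
    var_s <- var_s + (s[i] - mean_s)^2 / n
    cov_os <- cov_os + (o[i] - mean_o) * (s[i] - mean_s) / n
  }
  r <- cov_os / sqrt(var_o * var_s)

  msor <- 0
  for (i in 1:n) msor <- msor + (s[i] / o[i]) / n
  vr <- 0
  for (i in 1:n) vr <- vr + (s[i] / o[i] - msor)^2 / n
  cv_so_pct <- 100 * sqrt(vr) / msor

  mb_pct <- 100 * (mean_s - mean_o) / mean_o

  slope <- cov_os / var_s
  r2 <- r^2

  sse <- 0; sso <- 0
  for (i in 1:n) {
    sse <- sse + (s[i] - o[i])^2
    sso <- sso + (o[i] - mean_o)^2
  }
  me <- 1 - sse / sso

  mspe <- sse / n
  bias <- (mean_s - mean_o)^2
  slope_comp <- var_s * (1 - slope)^2
  random <- (1 - r^2) * var_o
  if (mspe > 0) {
    bias_pct <- 100 * bias / mspe
    slope_pct <- 100 * slope_comp / mspe
    random_pct <- 100 * random / mspe
  } else {
    bias_pct <- slope_pct <- random_pct <- 0
  }

  denom <- var_o + var_s + (mean_s - mean_o)^2
  ccc <- 2 * cov_os / denom
  ca <- 2 * sqrt(var_o) * sqrt(var_s) / denom

  os <- 0; ss <- 0
  for (i in 1:n) { os <- os + o[i] * s[i]; ss <- ss + s[i]^2 }
  slope_origin <- os / ss

  list(msor = msor, cv_so_pct = cv_so_pct, mb_pct = mb_pct,
       slope = slope, slope_origin = slope_origin, r2 = r2, me = me,
       mspe = mspe, bias_pct = bias_pct, slope_pct = slope_pct,
       random_pct = random_pct, ccc = ccc, ca = ca, r = r)
}

# random positive paired series with occasional strong correlation
random_paired <- function(n) {
  o <- exp(stats::rnorm(n, log(5), 0.4))
  s <- o * exp(stats::rnorm(1, 0, 0.3)) * exp(stats::rnorm(n, 0, 0.3))
  paired_series(o, s, variable = "dmi")
}
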