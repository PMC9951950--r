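# Agreement statistics for paired observed (O) / simulated (S) series.
#
# All moments use the population convention (divide by n): this is the only
# convention under which the MSPE partition
#   MSPE = (Sbar - Obar)^2 + SD_s^2 (1 - b1)^2 + (1 - r^2) SD_o^2
# holds exactly, with b1 = cov_os / SD_s^2.

as_paired <- function(p) {
  if (inherits(p, "paired_series")) return(p)
  stop("expected a paired_series object", call. = FALSE)
}

#' Joint moments of a paired series
#'
#' Means, standard deviations, covariance and Pearson correlation of the
#' observed and simulated vectors. Population convention (divide by n) by
#' default; set \code{sample = TRUE} for the n-1 convention (cross-checks
#' only — downstream statistics assume population moments).
#'
#' @param p a \code{\link{paired_series}}.
#' @param sample use the sample (n-1) convention.
#' @return a list of class \code{moments}: \code{n}, \code{mean_o},
#'   \code{mean_s}, \code{sd_o}, \code{sd_s}, \code{cov_os}, \code{r}
#'   (\code{NA} when either series is constant).
#' @export
moments <- function(p, sample = FALSE) {
  p <- as_paired(p)
  n <- length(p$o)
  if (n < 2L) stop("need at least 2 pairs to compute moments", call. = FALSE)
  denom <- if (sample) n - 1 else n
  mean_o <- mean(p$o)
  mean_s <- mean(p$s)
  var_o <- sum((p$o - mean_o)^2) / denom
  var_s <- sum((p$s - mean_s)^2) / denom
  cov_os <- sum((p$o - mean_o) * (p$s - mean_s)) / denom
  sd_o <- sqrt(var_o)
  sd_s <- sqrt(var_s)
  r <- if (sd_o > 0 && sd_s > 0) cov_os / (sd_o * sd_s) else NA_real_
  structure(list(n = n, mean_o = mean_o, mean_s = mean_s,
                 sd_o = sd_o, sd_s = sd_s, cov_os = cov_os, r = r),
            class = "moments")
}

#' Mean S/O ratio and its coefficient of variation
#'
#' The mean of the elementwise simulated-to-observed ratios (MSOR; 1 is
#' perfect accuracy, below 1 underestimation) and the coefficient of
#' variation of the ratios (precision; population SD over MSOR, in percent).
#'
#' @param p a \code{\link{paired_series}}.
#' @return list with \code{msor} and \code{cv_so_pct}.
#' @export
mean_so_ratio <- function(p) {
  p <- as_paired(p)
  ratio <- p$s / p$o
  msor <- mean(ratio)
  sd_ratio <- sqrt(mean((ratio - msor)^2))
  list(msor = msor, cv_so_pct = 100 * sd_ratio / msor)
}

#' Mean bias as a percentage of the observed mean
#'
#' \code{100 * (mean(S) - mean(O)) / mean(O)}: negative values mean the
#' simulation underestimates the observations on average.
#'
#' @param p a \code{\link{paired_series}}.
#' @return signed mean bias, percent.
#' @export
mean_bias_pct <- function(p) {
  p <- as_paired(p)
  m <- moments(p)
  100 * (m$mean_s - m$mean_o) / m$mean_o
}

#' Regression of observed on simulated values
#'
#' Two parameterizations of the accuracy slope: \code{mode = "moment"} is the
#' ordinary least-squares slope of O on S, \code{cov_os / SD_s^2}; \code{mode
#' = "origin"} is the zero-intercept slope \code{sum(O*S) / sum(S^2)}. A
#' slope of 1 is perfect accuracy. Two-sided t-tests of the slope against 1
#' and against 0 use n-2 (moment) or n-1 (origin) degrees of freedom. R^2 is
#' the squared Pearson correlation in both modes.
#'
#' @param p a \code{\link{paired_series}}.
#' @param mode \code{"moment"} (default) or \code{"origin"}.
#' @return list with \code{slope}, \code{slope_se}, \code{r2},
#'   \code{p_slope_vs_1}, \code{p_slope_vs_0}.
#' @export
regression_fit <- function(p, mode = c("moment", "origin")) {
  p <- as_paired(p)
  mode <- match.arg(mode)
  n <- length(p$o)
  if (n < 3L) stop("need at least 3 pairs for regression", call. = FALSE)
  m <- moments(p)
  if (mode == "moment") {
    if (m$sd_s == 0) stop("simulated values are constant: slope undefined",
                          call. = FALSE)
    slope <- m$cov_os / m$sd_s^2
    intercept <- m$mean_o - slope * m$mean_s
    resid <- p$o - intercept - slope * p$s
    df <- n - 2L
    slope_se <- sqrt((sum(resid^2) / df) / (n * m$sd_s^2))
  } else {
    ss <- sum(p$s^2)
    if (ss == 0) stop("simulated values are all zero: slope undefined",
                      call. = FALSE)
    slope <- sum(p$o * p$s) / ss
    resid <- p$o - slope * p$s
    df <- n - 1L
    slope_se <- sqrt((sum(resid^2) / df) / ss)
  }
  r2 <- if (is.na(m$r)) NA_real_ else m$r^2
  list(slope = slope, slope_se = slope_se, r2 = r2,
       p_slope_vs_1 = slope_pvalue(slope, 1, slope_se, df),
       p_slope_vs_0 = slope_pvalue(slope, 0, slope_se, df))
}

# exact-fit guard: se = 0 makes the t statistic degenerate
slope_pvalue <- function(slope, null, se, df) {
  if (se == 0) return(if (slope == null) 1 else 0)
  2 * stats::pt(abs((slope - null) / se), df = df, lower.tail = FALSE)
}

#' Model efficiency
#'
#' \code{ME = 1 - sum((S - O)^2) / sum((O - mean(O))^2)}: 1 is a perfect fit,
#' 0 matches the precision of predicting the observed mean, and negative
#' values mean the model is worse than the mean predictor.
#'
#' @param p a \code{\link{paired_series}}.
#' @return model efficiency (unbounded below).
#' @export
model_efficiency <- function(p) {
  p <- as_paired(p)
  sso <- sum((p$o - mean(p$o))^2)
  if (sso == 0) stop("observed values are constant: ME undefined",
                     call. = FALSE)
  1 - sum((p$s - p$o)^2) / sso
}

#' Mean square prediction error and its partition
#'
#' \code{MSPE = mean((S - O)^2)}, decomposed exactly (population moments)
#' into overall bias \code{(Sbar - Obar)^2}, slope deviation
#' \code{SD_s^2 (1 - b1)^2} with \code{b1 = cov_os / SD_s^2}, and random
#' variation \code{(1 - r^2) SD_o^2}; the three shares sum to 100\%. The
#' overall-bias significance is a two-sided paired t-test of O against S.
#'
#' @param p a \code{\link{paired_series}}.
#' @return list with \code{mspe}, \code{bias_pct}, \code{slope_pct},
#'   \code{random_pct}, \code{p_bias}, and logical \code{perfect_fit} (when
#'   MSPE is 0 the shares are reported as 0 and flagged, not an error).
#' @export
mspe_partition <- function(p) {
  p <- as_paired(p)
  n <- length(p$o)
  if (n < 3L) stop("need at least 3 pairs for the MSPE partition",
                   call. = FALSE)
  m <- moments(p)
  d <- p$s - p$o
  mspe <- mean(d^2)
  p_bias <- if (stats::sd(d) == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    stats::t.test(p$o, p$s, paired = TRUE)$p.value
  }
  if (mspe == 0) {
    return(list(mspe = 0, bias_pct = 0, slope_pct = 0, random_pct = 0,
                p_bias = p_bias, perfect_fit = TRUE))
  }
  bias <- (m$mean_s - m$mean_o)^2
  if (m$sd_s > 0) {
    b1 <- m$cov_os / m$sd_s^2
    slope_comp <- m$sd_s^2 * (1 - b1)^2
    random <- (1 - m$r^2) * m$sd_o^2
  } else {
    # constant predictor: no slope information, everything beyond the mean
    # shift is random
    slope_comp <- 0
    random <- m$sd_o^2
  }
  list(mspe = mspe,
       bias_pct = 100 * bias / mspe,
       slope_pct = 100 * slope_comp / mspe,
       random_pct = 100 * random / mspe,
       p_bias = p_bias, perfect_fit = FALSE)
}

#' Lin's concordance correlation coefficient
#'
#' \code{CCC = 2 cov_os / (SD_o^2 + SD_s^2 + (Sbar - Obar)^2)}, factored into
#' an accuracy component \code{Ca} (penalizing location and scale shift) and
#' the precision component \code{r} (Pearson correlation):
#' \code{CCC = Ca * r} to machine precision.
#'
#' @param p a \code{\link{paired_series}}.
#' @return list with \code{ccc}, \code{ca}, \code{r}.
#' @export
concordance <- function(p) {
  p <- as_paired(p)
  m <- moments(p)
  if (m$sd_o == 0 || m$sd_s == 0) {
    stop("zero variance in observed or simulated values: CCC undefined",
         call. = FALSE)
  }
  denom <- m$sd_o^2 + m$sd_s^2 + (m$mean_s - m$mean_o)^2
  list(ccc = 2 * m$cov_os / denom,
       ca = 2 * m$sd_o * m$sd_s / denom,
       r = m$r)
}

#' Evaluate every agreement descriptor on one paired series
#'
#' Assembles the full accuracy (MSOR, slope, mean bias), precision (CV of
#' S/O, R^2, model efficiency) and combined (MSPE partition, concordance)
#' descriptor set, with the overall-bias and slope significance tests.
#'
#' @param p a \code{\link{paired_series}} of length >= 3.
#' @param mode slope parameterization, see \code{\link{regression_fit}}.
#' @return an object of class \code{metric_set}; a named list whose fields
#'   are \code{n}, \code{msor}, \code{slope}, \code{slope_se}, \code{mb_pct},
#'   \code{cv_so_pct}, \code{r2}, \code{me}, \code{mspe}, \code{bias_pct},
#'   \code{slope_pct}, \code{random_pct}, \code{ccc}, \code{ca}, \code{r},
#'   \code{p_bias}, \code{p_slope_vs_1}, \code{p_slope_vs_0},
#'   \code{perfect_fit}.
#' @export
evaluate <- function(p, mode = c("moment", "origin")) {
  p <- as_paired(p)
  mode <- match.arg(mode)
  n <- length(p$o)
  if (n < 3L) stop("need at least 3 pairs to evaluate", call. = FALSE)
  so <- mean_so_ratio(p)
  reg <- regression_fit(p, mode)
  part <- mspe_partition(p)
  cc <- concordance(p)
  structure(list(n = n,
                 msor = so$msor,
                 slope = reg$slope,
                 slope_se = reg$slope_se,
                 mb_pct = mean_bias_pct(p),
                 cv_so_pct = so$cv_so_pct,
                 r2 = reg$r2,
                 me = model_efficiency(p),
                 mspe = part$mspe,
                 bias_pct = part$bias_pct,
                 slope_pct = part$slope_pct,
                 random_pct = part$random_pct,
                 ccc = cc$ccc,
                 ca = cc$ca,
                 r = cc$r,
                 p_bias = part$p_bias,
                 p_slope_vs_1 = reg$p_slope_vs_1,
                 p_slope_vs_0 = reg$p_slope_vs_0,
                 perfect_fit = part$perfect_fit,
                 mode = mode),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("metric_set (n =", x$n, ", slope mode =", x$mode, ")\n")
  fmt <- function(v) formatC(v, digits = 4, format = "g")
  cat("  accuracy : MSOR", fmt(x$msor), " slope", fmt(x$slope),
      " MB%", fmt(x$mb_pct), "\n")
  cat("  precision: CV%", fmt(x$cv_so_pct), " R2", fmt(x$r2),
      " ME", fmt(x$me), "\n")
  cat("  combined : MSPE", fmt(x$mspe),
      sprintf(" partition %s/%s/%s", fmt(x$bias_pct), fmt(x$slope_pct),
              fmt(x$random_pct)),
      " CCC", fmt(x$ccc), "= Ca", fmt(x$ca), "x R", fmt(x$r), "\n")
  invisible(x)
}
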