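# frozen hand computations on O = [2,4,6], S = [1,4,7]:
#   means 4, 4; pop variances 8/3, 6; cov 4; r = 1
#   ratios 1/2, 1, 7/6 -> msor 8/9, pop SD of ratios sqrt(0.0802469...)
#   slope (O on S) = 4/6; origin slope = 60/66
#   ME = 1 - 2/8; MSPE = 2/3 with partition (0, 100, 0); CCC = Ca = 24/26
ref <- paired_series(c(2, 4, 6), c(1, 4, 7))

test_that("moments match hand values and the sample convention", {
  m <- moments(ref)
  expect_equal(m$n, 3L)
  expect_equal(m$mean_o, 4)
  expect_equal(m$mean_s, 4)
  expect_equal(m$sd_o^2, 8 / 3, tolerance = 1e-12)
  expect_equal(m$sd_s^2, 6, tolerance = 1e-12)
  expect_equal(m$cov_os, 4, tolerance = 1e-12)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$cov_os, m$r * m$sd_o * m$sd_s, tolerance = 1e-12)

  ms <- moments(ref, sample = TRUE)
  expect_equal(ms$sd_o, stats::sd(ref$o))
  expect_equal(ms$cov_os, stats::cov(ref$o, ref$s))

  ident <- paired_series(1:3, 1:3)
  mi <- moments(ident)
  expect_equal(mi$r, 1)
  expect_equal(mi$sd_o, mi$sd_s)
  expect_true(is.na(moments(paired_series(c(1, 2), c(3, 3)))$r))
  expect_error(moments(paired_series(1, 1)), "at least 2")
})

test_that("mean S/O ratio and its CV match hand values", {
  so <- mean_so_ratio(ref)
  expect_equal(so$msor, 8 / 9, tolerance = 1e-12)
  expect_equal(so$cv_so_pct, 100 * sqrt(13 / 162) / (8 / 9),
               tolerance = 1e-12)
  expect_equal(round(so$cv_so_pct, 1), 31.9)

  same <- paired_series(c(2, 4, 6), c(2, 4, 6))
  expect_equal(mean_so_ratio(same), list(msor = 1, cv_so_pct = 0))
  scaled <- paired_series(c(2, 4, 6), 2 * c(2, 4, 6))
  expect_equal(mean_so_ratio(scaled), list(msor = 2, cv_so_pct = 0))
})

test_that("mean bias is signed so underestimation is negative", {
  expect_equal(mean_bias_pct(ref), 0)
  expect_equal(mean_bias_pct(paired_series(c(2, 4, 6), c(2, 4, 6))), 0)
  # underestimating simulation: means 159 observed vs 110 simulated
  under <- paired_series(c(150, 159, 168), c(101, 110, 119))
  expect_equal(mean_bias_pct(under), 100 * (110 - 159) / 159,
               tolerance = 1e-12)
  expect_lt(mean_bias_pct(under), 0)
})

test_that("regression slopes match hand values in both modes", {
  fit <- regression_fit(ref, "moment")
  expect_equal(fit$slope, 2 / 3, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # exact fit: slope se collapses, test vs 1 rejects, vs 2/3 accepts
  expect_equal(fit$slope_se, 0)
  expect_equal(fit$p_slope_vs_1, 0)

  origin <- regression_fit(ref, "origin")
  expect_equal(origin$slope, 60 / 66, tolerance = 1e-12)

  same <- paired_series(c(2, 4, 6), c(2, 4, 6))
  fit_same <- regression_fit(same, "moment")
  expect_equal(fit_same$slope, 1)
  expect_equal(fit_same$p_slope_vs_1, 1)

  # moment mode agrees with lm() on noisy data
  set.seed(3)
  p <- random_paired(12)
  fit <- regression_fit(p, "moment")
  lm_fit <- summary(stats::lm(p$o ~ p$s))
  expect_equal(fit$slope, unname(lm_fit$coefficients["p$s", 1]),
               tolerance = 1e-10)
  expect_equal(fit$slope_se, unname(lm_fit$coefficients["p$s", 2]),
               tolerance = 1e-10)
  expect_equal(fit$p_slope_vs_0,
               unname(lm_fit$coefficients["p$s", 4]), tolerance = 1e-10)
  lm0 <- summary(stats::lm(p$o ~ p$s + 0))
  f0 <- regression_fit(p, "origin")
  expect_equal(f0$slope, unname(lm0$coefficients[1, 1]), tolerance = 1e-10)
  expect_equal(f0$slope_se, unname(lm0$coefficients[1, 2]),
               tolerance = 1e-10)

  expect_error(regression_fit(paired_series(c(1, 2, 3), c(5, 5, 5))),
               "constant")
  expect_error(regression_fit(paired_series(c(1, 2), c(1, 2))),
               "at least 3")
})

test_that("model efficiency matches its definition and baselines", {
  expect_equal(model_efficiency(ref), 0.75, tolerance = 1e-12)
  expect_equal(model_efficiency(paired_series(c(2, 4, 6), c(2, 4, 6))), 1)
  # predicting the observed mean scores exactly zero
  expect_equal(model_efficiency(paired_series(c(2, 4, 6), c(4, 4, 4))), 0)
  expect_error(model_efficiency(paired_series(c(3, 3, 3), c(1, 2, 3))),
               "constant")
})

test_that("MSPE partition matches hand values and flags perfect fits", {
  part <- mspe_partition(ref)
  expect_equal(part$mspe, 2 / 3, tolerance = 1e-12)
  expect_equal(part$bias_pct, 0, tolerance = 1e-9)
  expect_equal(part$slope_pct, 100, tolerance = 1e-9)
  expect_equal(part$random_pct, 0, tolerance = 1e-9)
  expect_false(part$perfect_fit)
  expect_equal(part$p_bias,
               stats::t.test(ref$o, ref$s, paired = TRUE)$p.value)

  perfect <- mspe_partition(paired_series(c(2, 4, 6), c(2, 4, 6)))
  expect_true(perfect$perfect_fit)
  expect_equal(perfect$mspe, 0)
  expect_equal(perfect$bias_pct + perfect$slope_pct + perfect$random_pct, 0)

  # constant predictor: bias + random account for everything
  const <- mspe_partition(paired_series(c(2, 4, 6), c(3, 3, 3)))
  expect_equal(const$bias_pct + const$slope_pct + const$random_pct, 100,
               tolerance = 1e-9)
})

test_that("concordance matches hand values and its factorization", {
  cc <- concordance(ref)
  expect_equal(cc$ccc, 24 / 26, tolerance = 1e-12)
  expect_equal(cc$ca, 24 / 26, tolerance = 1e-12)
  expect_equal(cc$r, 1, tolerance = 1e-12)
  expect_equal(cc$ccc, cc$ca * cc$r, tolerance = 1e-12)
  expect_error(concordance(paired_series(c(1, 2, 3), c(5, 5, 5))),
               "zero variance")
})

test_that("evaluate assembles a complete, perfect-scoring identity fit", {
  ms <- evaluate(ref)
  expect_s3_class(ms, "metric_set")
  expect_equal(ms$msor, 8 / 9, tolerance = 1e-12)
  expect_equal(ms$slope, 2 / 3, tolerance = 1e-12)
  expect_equal(ms$mb_pct, 0)
  expect_equal(ms$me, 0.75, tolerance = 1e-12)
  expect_equal(ms$mspe, 2 / 3, tolerance = 1e-12)
  expect_equal(ms$ccc, 24 / 26, tolerance = 1e-12)

  o <- c(3.1, 4.2, 5.3, 6.4, 7.5)
  perfect <- evaluate(paired_series(o, o))
  expect_equal(perfect$msor, 1)
  expect_equal(perfect$mb_pct, 0)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$me, 1)
  expect_equal(perfect$mspe, 0)
  expect_true(perfect$perfect_fit)
  expect_equal(perfect$ccc, 1)
  expect_equal(perfect$ca, 1)
  expect_equal(perfect$r, 1)
})

test_that("every statistic matches the brute-force oracle on random data", {
  set.seed(202)
  for (k in 1:200) {
    p <- random_paired(sample(3:30, 1))
    want <- oracle_metrics(p$o, p$s)
    got <- evaluate(p, "moment")
    for (f in c("msor", "cv_so_pct", "mb_pct", "slope", "r2", "me",
                "mspe", "bias_pct", "slope_pct", "random_pct",
                "ccc", "ca", "r")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, info = f)
    }
    expect_equal(regression_fit(p, "origin")$slope, want$slope_origin,
                 tolerance = 1e-10)
  }
})

test_that("partition, factorization and bound invariants hold broadly", {
  set.seed(77)
  for (k in 1:50) {
    p <- random_paired(sample(3:25, 1))
    ms <- evaluate(p)
    expect_equal(ms$bias_pct + ms$slope_pct + ms$random_pct, 100,
                 tolerance = 1e-9)
    expect_equal(ms$ccc, ms$ca * ms$r, tolerance = 1e-12)
    expect_lte(abs(ms$r), 1)
    expect_lte(abs(ms$ccc), abs(ms$r) + 1e-12)
    expect_gt(ms$ca, 0)
    expect_lte(ms$ca, 1)
    expect_lte(ms$me, ms$r2 + 1e-12)
    # partition components reassemble MSPE itself
    m <- moments(p)
    expect_equal((ms$bias_pct + ms$slope_pct + ms$random_pct) / 100 * ms$mspe,
                 ms$mspe, tolerance = 1e-9)
  }
})

test_that("statistics are scale-equivariant", {
  set.seed(31)
  for (k in 1:20) {
    p <- random_paired(sample(3:20, 1))
    kscale <- runif(1, 0.1, 10)
    ps <- paired_series(kscale * p$o, kscale * p$s)
    a <- evaluate(p)
    b <- evaluate(ps)
    for (f in c("msor", "cv_so_pct", "mb_pct", "slope", "r2", "me",
                "bias_pct", "slope_pct", "random_pct", "ccc", "ca", "r")) {
      expect_equal(b[[f]], a[[f]], tolerance = 1e-9, info = f)
    }
    expect_equal(b$mspe, kscale^2 * a$mspe, tolerance = 1e-9)
  }
})
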