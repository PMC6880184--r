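test_that("trapezoid AUC of a triangle profile is the triangle area", {
  expect_equal(trapz(c(0, 1, 2), c(0, 100, 0)), 100)
  reg <- dose_regimen(dose = 1)
  # exponential tail appended so the terminal slope is estimable
  prof <- plasma_profile("x", c(0, 1, 2, 4, 8, 12),
                         c(0, 100, 50, 12.5, 0.78125, 0.048828125), reg)
  r <- nca(prof)
  expect_equal(r$cmax, 100)
  expect_equal(r$tmax, 1)
})

test_that("dense-grid NCA converges to the closed-form AUC and half-life", {
  pk <- ref_pk()
  reg <- dose_regimen(dose = 5)
  tt <- seq(0, 120, by = 0.01)
  prof <- plasma_profile("x", tt, pk_concentration(pk, reg, tt), reg)
  r <- nca(prof)
  closed <- mg_to_ng(5) / (pk$ke * pk$v_f)
  expect_equal(r$auc_0_inf, closed, tolerance = 0.005)
  expect_equal(r$t_half, log(2) / pk$ke, tolerance = 1e-3)
  expect_equal(r$lambda_z, pk$ke, tolerance = 1e-3)
  expect_equal(r$tmax, 3.29, tolerance = 0.01)
  expect_equal(r$cl_f, pk$cl_f, tolerance = 0.005)
})

test_that("missing 24 h sample is interpolated with a flag", {
  pk <- ref_pk()
  reg <- dose_regimen(dose = 5)
  tt <- c(0, 0.5, 1, 2, 4, 8, 12, 23, 30, 36, 48)
  prof <- plasma_profile("x", tt, pk_concentration(pk, reg, tt), reg)
  expect_warning(r <- nca(prof), "interpolated")
  expect_true(r$interpolated_24h)
  expect_false(is.na(r$auc_0_24))
})

test_that("tmax ties resolve to the earliest time", {
  reg <- dose_regimen(dose = 1)
  prof <- plasma_profile("x", c(0, 1, 2, 3, 5, 8, 12), c(0, 100, 100, 50, 12, 3, 0.7), reg)
  expect_equal(nca(prof)$tmax, 1)
})

test_that("accumulation ratio matches the geometric-series identity and the observed range", {
  pk <- ref_pk()
  expect_equal(accumulation_ratio(1000, 1000)$r_auc, 1.0)
  expect_error(accumulation_ratio(0, 10), "> 0")
  # elimination-only (bolus) steady-state identity
  expect_equal(1 / (1 - exp(-24 * pk$ke)), 1.1742, tolerance = 1e-4)
  # oral-model accumulation: steady-state daily AUC equals the single-dose
  # AUC0-inf, so R = AUC0-inf / AUC0-24(day 1); absorption carryover makes
  # this slightly larger than the bolus identity
  reg <- dose_regimen(dose = 5, interval = 24, n_doses = 60)
  auc1 <- pk_auc(pk, reg, 0, 24)
  auc_ss <- pk_auc(pk, reg, 59 * 24, 60 * 24)
  r_oracle <- (mg_to_ng(5) / (pk$ke * pk$v_f)) / auc1
  expect_equal(accumulation_ratio(auc1, auc_ss)$r_auc, r_oracle, tolerance = 1e-4)
  expect_equal(r_oracle, 1.1983, tolerance = 1e-4)
  # sits inside the observed multiple-dose range 1.18-1.22
  expect_gt(r_oracle, 1.15); expect_lt(r_oracle, 1.25)
  # reported day-7/day-1 ratio at the 2 mg dose
  expect_equal(accumulation_ratio(2195, 2680)$r_auc, 1.22, tolerance = 0.005)
})

test_that("power model recovers exact exponents and flags thin designs", {
  d <- c(0.5, 1, 2, 5, 10, 20)
  expect_equal(dose_proportionality(d, 7 * d)$slope, 1.0, tolerance = 1e-12)
  expect_equal(dose_proportionality(d, 3 * d^2)$slope, 2.0, tolerance = 1e-12)
  expect_lt(dose_proportionality(d, 7 * d)$residual_ss, 1e-20)
  # noise-free model Cmax is exactly dose-proportional
  pk <- ref_pk()
  cmax <- vapply(d, function(dd) {
    tmax <- log(pk$ka / pk$ke) / (pk$ka - pk$ke)
    pk_concentration(pk, dose_regimen(dd), tmax)
  }, numeric(1))
  fit <- dose_proportionality(d, cmax)
  expect_equal(fit$slope, 1.0, tolerance = 1e-10)
  expect_error(dose_proportionality(c(1, 1, 2), c(5, 5, 10)), "insufficient")
})

test_that("geometric mean ratio matches the paired-t closed form", {
  expect_equal(geometric_mean_ratio(c(5, 9, 2), c(5, 9, 2))$gmr, 1.0)
  r <- geometric_mean_ratio(rep(80, 4), rep(100, 4))
  expect_equal(r$gmr, 0.8)
  expect_equal(diff(r$ci90), 0)
  # hand-computed paired-t interval on the log scale for 6 pairs
  test <- c(90, 75, 110, 80, 95, 70); ref <- c(100, 100, 100, 100, 100, 100)
  d <- log(test) - log(ref)
  tq <- qt(0.95, 5)
  expected <- exp(mean(d) + c(-1, 1) * tq * sd(d) / sqrt(6))
  r2 <- geometric_mean_ratio(test, ref)
  expect_equal(r2$ci90, expected, tolerance = 1e-12)
  expect_error(geometric_mean_ratio(c(1, -2), c(1, 1)), "positive")
})
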