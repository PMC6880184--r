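test_that("noise-free Emax fit recovers the generating parameters from perturbed starts", {
  pd <- ref_pd()
  cp <- c(10, 25, 50, 100, 200, 400, 800, 1600)
  eff <- effect_fraction(pd, cp)
  fit <- fit_emax(cp, eff, init = emax_params(emax = 0.9, ec50 = 400))
  expect_equal(fit$emax, 0.51, tolerance = 1e-6)
  expect_equal(fit$ec50, 196, tolerance = 1e-6)
  expect_lt(attr(fit, "rss"), 1e-12)
})

test_that("recovery holds over a grid of generating Emax and EC50", {
  cp <- c(10, 30, 80, 200, 500, 1200, 3000)
  for (em in c(0.1, 0.5, 0.9)) {
    for (ec in c(50, 300, 1000)) {
      truth <- emax_params(em, ec)
      fit <- fit_emax(cp, effect_fraction(truth, cp))
      expect_equal(fit$emax, em, tolerance = 1e-4)
      expect_equal(fit$ec50, ec, tolerance = 1e-4)
    }
  }
})

test_that("concentration rescaling moves EC50 and leaves Emax fixed", {
  pd <- ref_pd()
  cp <- c(10, 25, 50, 100, 200, 400, 800, 1600)
  eff <- effect_fraction(pd, cp)
  fit <- fit_emax(3 * cp, eff)
  expect_equal(fit$emax, 0.51, tolerance = 1e-6)
  expect_equal(fit$ec50, 3 * 196, tolerance = 1e-4)
})

test_that("degenerate effect data are rejected", {
  expect_error(fit_emax(c(10, 100, 1000), c(0, 0, 0)), "non-identifiable")
  expect_error(fit_emax(c(10, 10, 10), c(0.1, 0.2, 0.3)), "distinct")
})

test_that("interval means reproduce constants and are self-consistent noise-free", {
  phys <- ref_phys()
  pd <- ref_pd()
  pk <- ref_pk()
  # constant plasma concentration over a window averages to itself
  tt <- seq(0, 48, by = 0.5)
  ur <- data.frame(t_start = c(0, 6, 12, 24, 36), t_end = c(6, 12, 24, 36, 48),
                   xu_mg = NA_real_)
  # build urine and SUA from a fine-step simulation so discretization is small
  course <- simulate_sua(phys, pd, pk, dose_regimen(5),
                         sim_config(dt = 0.25, horizon = 48, start = -24,
                                    record_intervals = Map(c, ur$t_start, ur$t_end)))
  ur$xu_mg <- course$intervals$xu_mg
  sua_t <- course$times[course$times >= 0]
  sua_v <- course$sua[course$times >= 0]
  cps <- pk_concentration(pk, dose_regimen(5), tt)
  im <- interval_means(tt, cps, ur, sua_t, sua_v, phys)
  expect_equal(nrow(im), 4)
  # back-calculated effect tracks the model effect at the window-mean
  # concentration up to the interval-averaging approximation
  expect_equal(im$effect, effect_fraction(pd, im$cp_mean), tolerance = 0.15)
  expect_true(all(im$effect >= 0 & im$effect < 1))
  # constant-concentration window mean is exact
  flat <- interval_means(tt, rep(7, length(tt)), ur, sua_t, sua_v, phys)
  expect_equal(flat$cp_mean, rep(7, 4))
})

test_that("placebo interval means back-calculate to zero effect", {
  phys <- ref_phys()
  pd <- ref_pd()
  pk <- ref_pk()
  course <- simulate_sua(phys, pd, pk, dose_regimen(0),
                         sim_config(dt = 0.5, horizon = 48, start = -24,
                                    record_intervals = list(c(0, 6), c(6, 12),
                                                            c(12, 24), c(24, 48))))
  ur <- data.frame(t_start = course$intervals$t_start,
                   t_end = course$intervals$t_end,
                   xu_mg = course$intervals$xu_mg)
  tt <- seq(0, 48, by = 1)
  im <- interval_means(tt, rep(0, length(tt)), ur,
                       course$times, course$sua, phys)
  expect_equal(im$effect, rep(0, 4), tolerance = 1e-8)
  expect_equal(im$clr_mean, rep(7.10, 4), tolerance = 1e-6)
})

test_that("windows without coverage raise missing-interval errors", {
  phys <- ref_phys()
  ur <- data.frame(t_start = 0, t_end = 6, xu_mg = 10)
  expect_error(
    interval_means(c(0, 48), c(1, 1), ur, c(0, 48), c(5.7, 5.7), phys),
    "missing interval")
})
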