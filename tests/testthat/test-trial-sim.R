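test_that("placebo stays exactly at the baseline steady state", {
  course <- simulate_sua(ref_phys(), ref_pd(), ref_pk(), dose_regimen(0),
                         sim_config(horizon = 48))
  expect_equal(course$sua, rep(5.71, length(course$sua)), tolerance = 1e-12)
  expect_lt(mass_balance_residual(course), 1e-8)
})

test_that("every simulated trajectory conserves urate mass", {
  phys <- ref_phys(); pd <- ref_pd(); pk <- ref_pk()
  for (dose in c(0.5, 5, 20)) {
    course <- simulate_sua(phys, pd, pk, dose_regimen(dose, n_doses = 3),
                           sim_config(horizon = 96,
                                      record_intervals = list(c(-24, 0), c(0, 24))))
    expect_lt(mass_balance_residual(course), 1e-8)
    expect_true(all(course$ua_pool >= 0))
    expect_equal(course$sua, course$ua_pool / phys$vd_ua * 100, tolerance = 1e-14)
  }
})

test_that("constant-concentration runs converge to the closed-form steady state", {
  phys <- ref_phys(); pd <- ref_pd()
  for (cp in c(50, 200, 1000)) {
    ss <- steady_state_sua(phys, pd, cp)
    course <- simulate_sua(phys, pd, ref_pk(), dose_regimen(0),
                           sim_config(dt = 0.25, horizon = 120, start = 0,
                                      record_intervals = list(c(0, 24))),
                           cp_constant = cp)
    expect_equal(course$sua[length(course$sua)], ss, tolerance = 1e-3)
  }
  # baseline closure and linearity of the closed form
  expect_equal(steady_state_sua(phys, pd, 0), 5.71)
  phys2 <- phys; phys2$synthesis_rate <- 2 * phys$synthesis_rate
  expect_equal(steady_state_sua(phys2, pd, 0), 2 * 5.71)
})

test_that("higher clamped concentrations give pointwise lower SUA", {
  phys <- ref_phys(); pd <- ref_pd()
  cfg <- sim_config(dt = 0.5, horizon = 72, start = 0,
                    record_intervals = list(c(0, 24)))
  lo <- simulate_sua(phys, pd, ref_pk(), dose_regimen(0), cfg, cp_constant = 100)
  hi <- simulate_sua(phys, pd, ref_pk(), dose_regimen(0), cfg, cp_constant = 400)
  expect_true(all(hi$sua[-1] < lo$sua[-1] + 1e-12))
})

test_that("step-size refinement behaves as the schemes' orders predict", {
  phys <- ref_phys(); pd <- ref_pd(); pk <- ref_pk()
  reg <- dose_regimen(5, interval = 24, n_doses = 7)
  run <- function(dt, scheme) {
    simulate_sua(phys, pd, pk, reg,
                 sim_config(dt = dt, horizon = 168,
                            record_intervals = list(c(0, 24)), sua_at = scheme))
  }
  # start-of-step (hourly explicit) scheme: first-order convergence, i.e.
  # the dt = 1 vs 0.5 gap is about twice the dt = 0.5 vs 0.25 gap
  c1 <- run(1, "start"); c2 <- run(0.5, "start"); c4 <- run(0.25, "start")
  on2 <- c2$sua[match(c1$times, c2$times)]
  on4 <- c4$sua[match(c1$times, c4$times)]
  expect_equal(max(abs(c1$sua - on2)) / max(abs(on2 - on4)), 2, tolerance = 0.5)
  # midpoint scheme: halving dt moves every grid value by well under 0.5%
  m1 <- run(1, "midpoint"); m2 <- run(0.5, "midpoint")
  om2 <- m2$sua[match(m1$times, m2$times)]
  expect_lt(max(abs(m1$sua - om2) / m1$sua), 0.005)
  # both schemes land on the same trajectory in the fine-step limit
  m4 <- run(0.25, "midpoint")
  expect_equal(on4, m4$sua[match(c1$times, m4$times)], tolerance = 0.01)
})

test_that("interval accounting and dt divisibility are enforced", {
  phys <- ref_phys(); pd <- ref_pd(); pk <- ref_pk()
  expect_error(
    simulate_sua(phys, pd, pk, dose_regimen(5),
                 sim_config(dt = 1, horizon = 48,
                            record_intervals = list(c(0, 6.5)))),
    "does not divide")
  course <- simulate_sua(phys, pd, pk, dose_regimen(5), sim_config(horizon = 48))
  iv <- course$intervals
  # baseline interval reproduces steady-state throughput: synthesis x 24 h
  expect_equal(iv$xu_mg[1] + iv$xf_mg[1], phys$synthesis_rate * 24, tolerance = 1e-12)
  # interval sums account for every step in the window
  sel <- course$times[-length(course$times)] >= 0 & course$times[-1] <= 24
  expect_equal(iv$xu_mg[2], sum(course$xu_step[sel]))
})

test_that("multiple-dose prediction shows monotone troughs and dose ordering", {
  phys <- ref_phys(); pd <- ref_pd(); pk <- ref_pk()
  p2 <- predict_mad(phys, pd, pk, dose = 2)
  p5 <- predict_mad(phys, pd, pk, dose = 5)
  troughs <- function(p) vapply(1:7, function(d) {
    p$samples$sua_mg_dl[p$samples$time_h == 24 * d]
  }, numeric(1))
  expect_true(all(diff(troughs(p2)) < 1e-9))
  expect_lt(troughs(p5)[7], troughs(p2)[7])
  p0 <- predict_mad(phys, pd, pk, dose = 0)
  expect_equal(unique(round(p0$samples$sua_mg_dl, 10)), 5.71)
})

test_that("negative pool is reported as a physical inconsistency", {
  # absurdly small pool volume forces overdraw in one step
  phys <- urate_physiology(baseline_sua = 0.05, baseline_clr_ua = 7.10,
                           vd_ua = 30, f_reabs = 0.943)
  expect_error(
    simulate_sua(phys, ref_pd(), ref_pk(), dose_regimen(20),
                 sim_config(dt = 1, horizon = 24, start = 0,
                            record_intervals = list(c(0, 24)))),
    "negative|inconsistent")
})
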