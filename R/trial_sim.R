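#' Simulation configuration
#'
#' @param dt step width (h), default 1 (clearance is re-evaluated hourly)
#' @param horizon end of simulation (h, relative to the first dose at 0)
#' @param start start of simulation (h); default -24 so the baseline
#'   -24 to 0 h interval is emitted
#' @param record_intervals list of `c(start, end)` windows (h) for interval
#'   accounting; default -24-0, 0-24 and 24-48 h
#' @param sua_at `"start"` (default) to use start-of-step SUA and clearance
#'   for each step's excretion, or `"midpoint"` for a half-step predictor
#' @return a list of class `sim_config`
#' @export
sim_config <- function(dt = 1, horizon = 48, start = -24,
                       record_intervals = list(c(-24, 0), c(0, 24), c(24, 48)),
                       sua_at = c("start", "midpoint")) {
  stopifnot(dt > 0, horizon > start)
  sua_at <- match.arg(sua_at)
  structure(list(dt = dt, horizon = horizon, start = start,
                 record_intervals = record_intervals, sua_at = sua_at),
            class = "sim_config")
}

#' Forward simulation of the serum-urate time course
#'
#' Discrete conservative mass balance of the body urate pool under a dosing
#' regimen. Per step of width `dt`: the plasma drug concentration is the
#' exact analytic interval mean of the one-compartment curve; renal clearance
#' follows the Emax-attenuated reabsorption relation; excretion over the step
#' is `Xu = CLR * SUA * dt` and `Xf = CLGut * SUA * dt` (start-of-step SUA by
#' default); the pool updates as `pool += Synthesis*dt - Xu - Xf` and
#' `SUA = pool / Vd_UA`. Every milligram removed from the pool is credited to
#' an excretion route, so the balance closes to rounding error
#' (see [mass_balance_residual()]).
#'
#' The initial pool is `SUA0 * Vd_UA`; the physiology's baseline steady state
#' makes a placebo run exactly flat.
#'
#' @param phys a [urate_physiology()]
#' @param pd an [emax_params()]
#' @param pk a [pk_params()]
#' @param regimen a [dose_regimen()] (dose 0 simulates placebo)
#' @param cfg a [sim_config()]
#' @param cp_constant optional concentration clamp (ng/mL); when given, the
#'   PK model is ignored and `Cp` is held at this value for all t >= 0
#'   (used to test against the closed-form steady state)
#' @return an object of class `urate_time_course`: grid `times` (h), `sua`
#'   (mg/dL) and `ua_pool` (mg) per grid point; per-step `cp` (ng/mL),
#'   `clr_ua` (mL/min), `xu_step`, `xf_step` (mg); `intervals` data frame
#'   with `t_start`, `t_end`, `xu_mg`, `xf_mg`, `auec` (mg*h/dL)
#' @export
simulate_sua <- function(phys, pd, pk, regimen, cfg = sim_config(),
                         cp_constant = NULL) {
  stopifnot(inherits(phys, "urate_physiology"), inherits(pd, "emax_params"),
            inherits(cfg, "sim_config"))
  dt <- cfg$dt
  for (w in cfg$record_intervals) {
    if (any(abs((w - cfg$start) / dt - round((w - cfg$start) / dt)) > 1e-9)) {
      stop(sprintf("dt = %g h does not divide the interval boundary %g-%g h",
                   dt, w[1], w[2]))
    }
  }
  n <- round((cfg$horizon - cfg$start) / dt)
  times <- cfg$start + dt * (0:n)

  clgut_h <- ml_min_to_ml_h(phys$clgut_ua)                 # mL/h
  pool <- numeric(n + 1)
  pool[1] <- mg_dl_to_mg_ml(phys$baseline_sua) * phys$vd_ua  # mg
  cp <- clr <- xu <- xf <- numeric(n)

  for (i in seq_len(n)) {
    t0 <- times[i]; t1 <- times[i + 1]
    cp[i] <- if (!is.null(cp_constant)) {
      if (t1 <= 0) 0 else cp_constant
    } else if (regimen$dose > 0 && t1 > min(dose_times(regimen))) {
      pk_interval_mean(pk, regimen, t0, t1)
    } else 0
    clr[i] <- renal_clearance(phys, pd, cp[i])
    sua_ml <- pool[i] / phys$vd_ua                          # mg/mL
    if (cfg$sua_at == "midpoint") {
      half <- pool[i] + (phys$synthesis_rate -
        (ml_min_to_ml_h(clr[i]) + clgut_h) * sua_ml) * dt / 2
      sua_ml <- half / phys$vd_ua
    }
    xu[i] <- ml_min_to_ml_h(clr[i]) * sua_ml * dt           # mg
    xf[i] <- clgut_h * sua_ml * dt                          # mg
    pool[i + 1] <- pool[i] + phys$synthesis_rate * dt - xu[i] - xf[i]
    if (pool[i + 1] < 0) {
      stop("urate pool went negative: parameters are physically inconsistent at this step size")
    }
  }
  sua <- pool / phys$vd_ua * ML_PER_DL                      # mg/dL

  ivs <- lapply(cfg$record_intervals, function(w) {
    sel <- times[-(n + 1)] >= w[1] - 1e-9 & times[-1] <= w[2] + 1e-9
    data.frame(t_start = w[1], t_end = w[2],
               xu_mg = sum(xu[sel]), xf_mg = sum(xf[sel]),
               auec = trapz_window(times, sua, w[1], w[2]))
  })

  structure(list(times = times, sua = sua, ua_pool = pool,
                 cp = cp, clr_ua = clr, xu_step = xu, xf_step = xf,
                 intervals = do.call(rbind, ivs),
                 dt = dt, phys = phys, pd = pd, regimen = regimen),
            class = "urate_time_course")
}

#' Closed-form steady-state SUA under a constant drug concentration
#'
#' With `Cp` clamped, production balances clearance at
#' `SUA_ss = Synthesis / (CLR(Cp) + CLGut)` (unit-converted to mg/dL). The
#' independent oracle for the simulator's long-run behaviour.
#'
#' @param phys a [urate_physiology()]
#' @param pd an [emax_params()]
#' @param cp_const constant total plasma concentration (ng/mL), >= 0
#' @return steady-state SUA (mg/dL)
#' @export
steady_state_sua <- function(phys, pd, cp_const) {
  stopifnot(cp_const >= 0)
  clr_h <- ml_min_to_ml_h(renal_clearance(phys, pd, cp_const) + phys$clgut_ua)
  phys$synthesis_rate / clr_h * ML_PER_DL
}

#' Mass-balance residual of a simulated time course
#'
#' `|pool(end) - pool(0) - Synthesis*T + sum(Xu) + sum(Xf)|` over the whole
#' simulated span. The stepwise update is conservative by construction, so
#' this is zero up to floating-point rounding.
#'
#' @param course a [simulate_sua()] result
#' @return absolute residual (mg)
#' @export
mass_balance_residual <- function(course) {
  stopifnot(inherits(course, "urate_time_course"))
  T <- diff(range(course$times))
  abs(course$ua_pool[length(course$ua_pool)] - course$ua_pool[1] -
        course$phys$synthesis_rate * T +
        sum(course$xu_step) + sum(course$xf_step))
}

#' Predict the multiple-dose SUA profile at the MAD sampling schedule
#'
#' Runs [simulate_sua()] for once-daily dosing and samples the predicted
#' drug concentration and SUA at the multiple-ascending-dose blood schedule
#' (full profiles on days 1, 4 and 7; troughs on the other days; 36, 48 and
#' 72 h after the last dose), for overlay against observed data.
#'
#' @param phys a [urate_physiology()]
#' @param pd an [emax_params()]
#' @param pk a [pk_params()]
#' @param dose once-daily dose (mg)
#' @param days number of dosing days, default 7
#' @param dt simulation step (h), default 1
#' @return list with `samples` (data frame `time_h`, `day`, `cp_ng_ml`,
#'   `sua_mg_dl`) and the full `course`
#' @export
predict_mad <- function(phys, pd, pk, dose, days = 7, dt = 1) {
  regimen <- dose_regimen(dose = dose, interval = 24, n_doses = days)
  horizon <- (days - 1) * 24 + 72
  ivs <- c(list(c(-24, 0)), lapply(seq_len(days), function(d) c((d - 1) * 24, d * 24)))
  course <- simulate_sua(phys, pd, pk, regimen,
                         sim_config(dt = dt, horizon = horizon,
                                    record_intervals = ivs))
  tt <- mad_blood_times(days)
  cp <- if (dose > 0) pk_concentration(pk, regimen, tt) else numeric(length(tt))
  sua <- stats::approx(course$times, course$sua, xout = tt)$y
  list(samples = data.frame(time_h = tt, day = tt %/% 24,
                            cp_ng_ml = cp, sua_mg_dl = sua),
       course = course)
}

#' Blood-sampling times of the single-ascending-dose design
#'
#' 0 (pre-dose), 0.25, 0.5, 1, 1.5, 2, 4, 6, 8, 12, 24, 36 and 48 h.
#' @return numeric vector of times (h)
#' @export
sad_blood_times <- function() c(0, 0.25, 0.5, 1, 1.5, 2, 4, 6, 8, 12, 24, 36, 48)

#' Urine-collection windows of the single-ascending-dose design
#'
#' A 24 h pre-dose baseline collection, then 0-6, 6-12, 12-24, 24-36 and
#' 36-48 h.
#' @return list of `c(start, end)` (h)
#' @export
sad_urine_windows <- function() {
  list(c(-24, 0), c(0, 6), c(6, 12), c(12, 24), c(24, 36), c(36, 48))
}

#' Blood-sampling times of the multiple-ascending-dose design
#'
#' Full profiles (0.25-24 h post dose) on dosing days 1, 4 and 7; 12 and
#' 24 h troughs on days 2, 3, 5 and 6; 36, 48 and 72 h after the final dose;
#' plus the pre-first-dose sample.
#'
#' @param days number of once-daily dosing days, default 7
#' @return numeric vector of times (h) since the first dose
#' @export
mad_blood_times <- function(days = 7) {
  full <- c(0.25, 0.5, 1, 1.5, 2, 4, 6, 8, 12, 24)
  out <- 0
  for (d in seq_len(days) - 1) {
    base <- 24 * d
    out <- c(out, base + if (d %in% c(0, 3, days - 1)) full else c(12, 24))
  }
  out <- c(out, 24 * (days - 1) + c(36, 48, 72))
  sort(unique(out))
}
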