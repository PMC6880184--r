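#' One-compartment oral PK parameter set
#'
#' The apparent triplet of the one-compartment first-order-absorption model:
#' distribution volume `V/F` (mL), absorption rate constant `Ka` (1/h) and
#' elimination rate constant `Ke` (1/h). `Ka > Ke` is enforced by the fitter
#' (flip-flop resolution); the constructor only requires `Ka != Ke`.
#'
#' @param v_f apparent distribution volume (mL), > 0
#' @param ka first-order absorption rate constant (1/h), > 0
#' @param ke first-order elimination rate constant (1/h), > 0, != `ka`
#' @return an object of class `pk_params` with derived `t_half = ln(2)/ke`
#'   (h) and `cl_f = ke * v_f` (mL/h)
#' @export
pk_params <- function(v_f, ka, ke) {
  stopifnot(is.numeric(v_f), is.numeric(ka), is.numeric(ke),
            length(v_f) == 1, length(ka) == 1, length(ke) == 1,
            v_f > 0, ka > 0, ke > 0)
  if (ka == ke) {
    stop("degenerate parameters: ka == ke (the coincident-rate limit is not supported)")
  }
  structure(
    list(v_f = v_f, ka = ka, ke = ke,
         t_half = log(2) / ke, cl_f = ke * v_f),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat("One-compartment oral PK parameters\n")
  cat(sprintf("  V/F  = %.4g mL\n  Ka   = %.4g /h\n  Ke   = %.4g /h\n", x$v_f, x$ka, x$ke))
  cat(sprintf("  t1/2 = %.3g h, CL/F = %.4g mL/h\n", x$t_half, x$cl_f))
  invisible(x)
}

#' Dosing regimen
#'
#' @param dose amount per administration (mg), >= 0
#' @param interval dosing interval (h), > 0
#' @param n_doses number of administrations, >= 1
#' @param start_time clock time of the first dose (h)
#' @return an object of class `dose_regimen`
#' @export
dose_regimen <- function(dose, interval = 24, n_doses = 1, start_time = 0) {
  stopifnot(dose >= 0, interval > 0, n_doses >= 1, n_doses == round(n_doses))
  structure(list(dose = dose, interval = interval, n_doses = as.integer(n_doses),
                 start_time = start_time),
            class = "dose_regimen")
}

dose_times <- function(regimen) {
  regimen$start_time + regimen$interval * (seq_len(regimen$n_doses) - 1)
}

#' Observed or simulated plasma concentration profile
#'
#' @param subject_id subject label
#' @param times sampling times (h), strictly increasing
#' @param concentrations plasma drug concentrations (ng/mL), non-negative
#' @param regimen the [dose_regimen()] under which the profile was observed
#' @return an object of class `plasma_profile`
#' @export
plasma_profile <- function(subject_id, times, concentrations, regimen) {
  stopifnot(length(times) == length(concentrations),
            all(diff(times) > 0),
            all(concentrations >= 0),
            inherits(regimen, "dose_regimen"))
  structure(list(subject_id = subject_id, times = as.numeric(times),
                 concentrations = as.numeric(concentrations), regimen = regimen),
            class = "plasma_profile")
}

# single-dose concentration at time-after-dose dt (vectorized over dt);
# dose in mg, result ng/mL
onecomp_single <- function(params, dose_mg, dt) {
  d <- mg_to_ng(dose_mg)
  k <- params$ka / (params$ka - params$ke)
  out <- d / params$v_f * k * (exp(-params$ke * dt) - exp(-params$ka * dt))
  out[dt <= 0] <- 0
  out
}

# integral of the single-dose curve from dose time to time-after-dose dt
# (ng*h/mL); closed form of the exponential difference
onecomp_single_int <- function(params, dose_mg, dt) {
  d <- mg_to_ng(dose_mg)
  ka <- params$ka; ke <- params$ke
  k <- ka / (ka - ke)
  out <- d / params$v_f * k *
    ((1 - exp(-ke * dt)) / ke - (1 - exp(-ka * dt)) / ka)
  out[dt <= 0] <- 0
  out
}

#' Plasma concentration under a regimen (superposition)
#'
#' Sums time-shifted single-dose one-compartment curves over every dose given
#' at or before `t`. Zero before the first dose and continuous in `t`.
#'
#' @param params [pk_params()]
#' @param regimen [dose_regimen()]
#' @param t times (h), vectorized
#' @return concentrations (ng/mL)
#' @export
pk_concentration <- function(params, regimen, t) {
  stopifnot(inherits(params, "pk_params"), inherits(regimen, "dose_regimen"))
  td <- dose_times(regimen)
  out <- numeric(length(t))
  for (d in td) out <- out + onecomp_single(params, regimen$dose, t - d)
  out
}

#' Analytic AUC of the model curve over an interval
#'
#' Exact integral of the superposed one-compartment curve over
#' `[t0, t1]` — no quadrature error. Used by the urate simulator, which needs
#' interval-mean rather than point-sampled concentrations.
#'
#' @param params [pk_params()]
#' @param regimen [dose_regimen()]
#' @param t0,t1 interval bounds (h), `t1 > t0`
#' @return AUC (ng*h/mL)
#' @export
pk_auc <- function(params, regimen, t0, t1) {
  stopifnot(t1 > t0)
  td <- dose_times(regimen)
  total <- 0
  for (d in td) {
    total <- total +
      onecomp_single_int(params, regimen$dose, t1 - d) -
      onecomp_single_int(params, regimen$dose, t0 - d)
  }
  total
}

#' Interval-mean plasma concentration
#'
#' @inheritParams pk_auc
#' @return mean concentration over `[t0, t1]` (ng/mL)
#' @export
pk_interval_mean <- function(params, regimen, t0, t1) {
  pk_auc(params, regimen, t0, t1) / (t1 - t0)
}

#' Reference PK parameters for dotinurad in healthy adults
#'
#' The fasted-state one-compartment estimates from the first-in-human
#' single/multiple ascending dose programme of dotinurad:
#' V/F = 10585 mL, Ka = 0.770 /h, Ke = 0.0795 /h.
#'
#' @return a [pk_params()] object
#' @export
reference_pk_params <- function() pk_params(v_f = 10585, ka = 0.770, ke = 0.0795)
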