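#' Non-compartmental analysis of a single-dose plasma profile
#'
#' Model-free PK summary: Cmax/Tmax by maximum (ties resolved to the earliest
#' time), AUC by the linear trapezoidal rule on the observed points, terminal
#' slope `lambda_z` by log-linear regression on the terminal phase, with
#' `AUC0-inf = AUC0-last + Clast/lambda_z` and `CL/F = dose/AUC0-inf`.
#'
#' The terminal regression starts from the last three positive post-Tmax
#' points and extends backwards while the adjusted R-squared improves. If no
#' sample falls exactly at 24 h the 24 h concentration is interpolated
#' linearly between the bracketing samples and the result is flagged.
#'
#' @param profile a [plasma_profile()]
#' @param regimen optional [dose_regimen()]; defaults to the profile's own
#' @return an object of class `nca_result`: `cmax` (ng/mL), `tmax` (h),
#'   `auc_0_24`, `auc_0_last`, `auc_0_inf` (ng*h/mL), `lambda_z` (1/h),
#'   `t_half` (h), `cl_f` (mL/h), `n_lambda_points`,
#'   `interpolated_24h` flag
#' @export
nca <- function(profile, regimen = profile$regimen) {
  stopifnot(inherits(profile, "plasma_profile"))
  t <- profile$times
  y <- profile$concentrations

  imax <- which.max(y)          # which.max returns the first (earliest) max
  cmax <- y[imax]
  tmax <- t[imax]

  lz <- terminal_slope(t, y, tmax)
  if (lz$lambda_z <= 0) {
    stop("non-estimable terminal phase: log-linear slope is not negative")
  }

  auc_0_last <- trapz(t, y)
  interpolated <- FALSE
  if (max(t) >= 24) {
    if (any(t == 24)) {
      i24 <- t <= 24
      auc_0_24 <- trapz(t[i24], y[i24])
    } else {
      c24 <- stats::approx(t, y, xout = 24)$y
      interpolated <- TRUE
      i24 <- t < 24
      auc_0_24 <- trapz(c(t[i24], 24), c(y[i24], c24))
      warning("no 24 h sample; concentration at 24 h interpolated linearly")
    }
  } else {
    auc_0_24 <- NA_real_
  }

  c_last <- y[length(y)]
  auc_0_inf <- auc_0_last + c_last / lz$lambda_z
  cl_f <- mg_to_ng(regimen$dose) / auc_0_inf

  structure(list(
    cmax = cmax, tmax = tmax,
    auc_0_24 = auc_0_24, auc_0_last = auc_0_last, auc_0_inf = auc_0_inf,
    lambda_z = lz$lambda_z, t_half = log(2) / lz$lambda_z,
    cl_f = cl_f, n_lambda_points = lz$n, interpolated_24h = interpolated
  ), class = "nca_result")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# log-linear terminal regression: last 3 positive points after Tmax,
# extended backwards while adjusted R^2 improves
terminal_slope <- function(t, y, tmax) {
  ok <- which(t > tmax & y > 0)
  if (length(ok) < 3) stop("need >= 3 positive terminal points after Tmax for lambda_z")
  best <- NULL
  for (n in 3:length(ok)) {
    idx <- utils::tail(ok, n)
    fit <- stats::lm(log(y[idx]) ~ t[idx])
    r2 <- summary(fit)$adj.r.squared
    if (is.null(best) || r2 > best$r2 + 1e-12) {
      best <- list(lambda_z = -unname(stats::coef(fit)[2]), n = n, r2 = r2)
    } else {
      break
    }
  }
  best
}

#' Accumulation ratio of daily AUC
#'
#' Ratio of `AUC0-24` on a later day of once-daily dosing to `AUC0-24` on
#' day 1. For linear PK at steady state this equals `1/(1 - exp(-Ke * tau))`.
#'
#' @param auc_day1 AUC0-24 on day 1 (ng*h/mL), > 0
#' @param auc_dayN AUC0-24 on the later day (ng*h/mL), > 0
#' @return list with `r_auc`
#' @export
accumulation_ratio <- function(auc_day1, auc_dayN) {
  if (auc_day1 <= 0) stop("auc_day1 must be > 0")
  stopifnot(auc_dayN > 0)
  list(r_auc = auc_dayN / auc_day1)
}

#' Dose-proportionality power model
#'
#' Ordinary least squares of `log(metric)` on `log(dose)`:
#' `log(metric) = a + b * log(dose)`. A slope `b` near 1 with its 90%
#' confidence interval containing 1 supports dose proportionality.
#'
#' @param dose doses (mg), > 0, at least 3 distinct values
#' @param metric exposure metric (Cmax or AUC), > 0
#' @return list with `intercept`, `slope`, `slope_ci90` (t-based), `n`,
#'   `residual_ss`
#' @export
dose_proportionality <- function(dose, metric) {
  stopifnot(length(dose) == length(metric), all(metric > 0), all(dose > 0))
  if (length(unique(dose)) < 3) {
    stop("insufficient design: need >= 3 distinct doses for the power model")
  }
  fit <- stats::lm(log(metric) ~ log(dose))
  ci <- stats::confint(fit, "log(dose)", level = 0.90)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       slope_ci90 = as.numeric(ci),
       n = length(dose),
       residual_ss = sum(stats::resid(fit)^2))
}

#' Geometric mean ratio of paired exposures
#'
#' `exp(mean(log(test) - log(reference)))` with a 90% confidence interval
#' from the paired t distribution on the log scale, back-transformed. The
#' standard bioavailability comparison (e.g. fed vs fasted).
#'
#' @param test,reference paired positive values (same length, >= 2 pairs)
#' @return list with `gmr`, `ci90`, `n_pairs`
#' @export
geometric_mean_ratio <- function(test, reference) {
  stopifnot(length(test) == length(reference), length(test) >= 2)
  if (any(test <= 0) || any(reference <= 0)) {
    stop("geometric mean ratio requires strictly positive paired values")
  }
  d <- log(test) - log(reference)
  n <- length(d)
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  tq <- stats::qt(0.95, df = n - 1)
  list(gmr = exp(m), ci90 = exp(c(m - tq * se, m + tq * se)), n_pairs = n)
}
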