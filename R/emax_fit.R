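#' Interval means of concentration, clearance and back-calculated effect
#'
#' For each evaluation window, computes the trapezoidal interval-mean plasma
#' drug concentration, the area under the SUA curve (AUEC), the implied mean
#' renal urate clearance `Xu_UA/AUEC`, and the drug effect back-calculated
#' from the clearance relation:
#' `E = (CLR - GFR*(1 - f_reabs)) / (f_reabs * GFR)`, clipped to `[0, 1)`
#' with a warning when noise pushes it outside.
#'
#' @param times,concentrations plasma sampling times (h) and drug
#'   concentrations (ng/mL) covering every window
#' @param urine data frame with columns `t_start`, `t_end` (h) and `xu_mg`
#'   (urinary urate per collection, mg); collections must tile each window
#' @param sua_times,sua_values SUA sampling times (h) and values (mg/dL)
#'   covering every window
#' @param phys a [urate_physiology()] supplying `gfr` and `f_reabs`
#' @param windows list of `c(start, end)` windows (h); default the standard
#'   0-6, 6-12, 12-24, 24-48 h evaluation windows
#' @return data frame with one row per window: `t_start`, `t_end`,
#'   `cp_mean` (ng/mL), `auec` (mg*h/dL), `xu_mg`, `clr_mean` (mL/min),
#'   `effect`
#' @export
interval_means <- function(times, concentrations, urine, sua_times, sua_values,
                           phys,
                           windows = list(c(0, 6), c(6, 12), c(12, 24), c(24, 48))) {
  stopifnot(inherits(phys, "urate_physiology"),
            length(times) == length(concentrations),
            length(sua_times) == length(sua_values),
            all(c("t_start", "t_end", "xu_mg") %in% names(urine)))
  rows <- lapply(windows, function(w) {
    t0 <- w[1]; t1 <- w[2]
    if (min(times) > t0 || max(times) < t1) {
      stop(sprintf("missing interval: plasma samples do not cover %g-%g h", t0, t1))
    }
    if (min(sua_times) > t0 || max(sua_times) < t1) {
      stop(sprintf("missing interval: SUA samples do not cover %g-%g h", t0, t1))
    }
    inside <- urine$t_start >= t0 & urine$t_end <= t1
    covered <- sum(urine$t_end[inside] - urine$t_start[inside])
    if (abs(covered - (t1 - t0)) > 1e-9) {
      stop(sprintf("missing interval: urine collections do not tile %g-%g h", t0, t1))
    }
    cp_mean <- trapz_window(times, concentrations, t0, t1) / (t1 - t0)
    auec <- trapz_window(sua_times, sua_values, t0, t1)
    xu <- sum(urine$xu_mg[inside])
    clr <- clearance_from_excretion(xu, auec)
    eff <- (clr - phys$gfr * (1 - phys$f_reabs)) / (phys$f_reabs * phys$gfr)
    if (eff < 0 || eff >= 1) {
      if (eff < -1e-9 || eff >= 1 + 1e-9) {
        warning(sprintf("back-calculated effect %.3g outside [0, 1) in %g-%g h; clipped",
                        eff, t0, t1))
      }
      eff <- min(max(eff, 0), 1 - 1e-9)
    }
    data.frame(t_start = t0, t_end = t1, cp_mean = cp_mean, auec = auec,
               xu_mg = xu, clr_mean = clr, effect = eff)
  })
  do.call(rbind, rows)
}

# trapezoid over [t0, t1] with linear interpolation at the window edges
trapz_window <- function(x, y, t0, t1) {
  xs <- sort(unique(c(t0, t1, x[x > t0 & x < t1])))
  ys <- stats::approx(x, y, xout = xs)$y
  trapz(xs, ys)
}

#' Fit the simple Emax model to effect-vs-concentration points
#'
#' Least-squares fit of `E = Emax * Cp / (EC50 + Cp)` by
#' Levenberg-Marquardt with `Emax` bounded in `(0, 1]` and `EC50 > 0`.
#'
#' @param cp_mean interval-mean plasma concentrations (ng/mL); at least 3
#'   distinct values
#' @param effect observed effect fractions in `[0, 1)`
#' @param init optional [emax_params()] starting values; default `Emax` from
#'   the largest observed effect and `EC50` from the concentration nearest
#'   half that effect
#' @return an [emax_params()] with attributes `rss`, `cv_percent` (named
#'   asymptotic %CV), `converged`, `n_obs`
#' @export
fit_emax <- function(cp_mean, effect, init = NULL) {
  stopifnot(length(cp_mean) == length(effect), all(cp_mean >= 0),
            all(effect >= 0))
  if (length(unique(cp_mean)) < 3) {
    stop("need >= 3 distinct concentrations to identify Emax and EC50")
  }
  if (all(effect == 0)) {
    stop("non-identifiable: all effects are zero, EC50 is undetermined")
  }
  if (is.null(init)) {
    e0 <- min(max(effect) * 1.1, 0.99)
    c0 <- cp_mean[which.min(abs(effect - e0 / 2))]
    init <- emax_params(emax = e0, ec50 = max(c0, 1e-3))
  } else {
    stopifnot(inherits(init, "emax_params"))
  }
  fit <- minpack.lm::nlsLM(
    effect ~ emax * cp_mean / (ec50 + cp_mean),
    # a start pinned to the Emax bound stalls the constrained search
    start = list(emax = min(init$emax, 0.995), ec50 = init$ec50),
    lower = c(emax = 1e-9, ec50 = 1e-9), upper = c(emax = 1, ec50 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  cf <- stats::coef(fit)
  if (cf[["emax"]] >= 1 - 1e-9) {
    warning("Emax estimate is at the upper bound 1; effect saturation not identified")
  }
  est <- emax_params(emax = cf[["emax"]], ec50 = cf[["ec50"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  cv <- 100 * sqrt(pmax(diag(vc), 0)) / abs(cf)
  names(cv) <- c("emax", "ec50")
  attr(est, "rss") <- sum(stats::resid(fit)^2)
  attr(est, "cv_percent") <- cv
  attr(est, "converged") <- isTRUE(fit$convInfo$isConv %||% TRUE)
  attr(est, "n_obs") <- length(effect)
  est
}
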