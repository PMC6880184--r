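#' Urate-handling physiology
#'
#' The mass-balance constants of the serum-urate disposition model. Urate is
#' produced at a constant rate ("synthesis", diet plus endogenous), held in a
#' single well-mixed pool of volume `vd_ua`, and cleared by two parallel
#' routes: renal (glomerular filtration at `gfr` followed by fractional
#' tubular reabsorption `f_reabs`) and non-renal/gut (`clgut_ua`). Two
#' closures define the baseline state:
#' renal:non-renal excretion is 2:1, so `clgut_ua = baseline_clr_ua / 2`;
#' and the baseline is a steady state, so
#' `synthesis = (baseline_clr_ua + clgut_ua) * baseline_sua` (unit-consistent).
#'
#' @param baseline_sua baseline serum urate (mg/dL), > 0
#' @param baseline_clr_ua baseline renal urate clearance (mL/min), > 0
#' @param vd_ua urate distribution volume (mL), > 0
#' @param f_reabs fractional tubular reabsorption of filtered urate, in
#'   `[0, 1]`
#' @param gfr glomerular filtration rate (mL/min); if `NULL`, implied from
#'   `baseline_clr_ua` and `f_reabs` via [implied_gfr()]
#' @return an object of class `urate_physiology` with fields `vd_ua` (mL),
#'   `f_reabs`, `gfr` (mL/min), `clgut_ua` (mL/min), `synthesis_rate` (mg/h),
#'   `baseline_sua` (mg/dL), `baseline_clr_ua` (mL/min)
#' @export
urate_physiology <- function(baseline_sua, baseline_clr_ua, vd_ua, f_reabs,
                             gfr = NULL) {
  stopifnot(baseline_sua > 0, baseline_clr_ua > 0, vd_ua > 0,
            f_reabs >= 0, f_reabs <= 1)
  if (is.null(gfr)) gfr <- implied_gfr(baseline_clr_ua, f_reabs)
  stopifnot(gfr > 0)
  clgut <- baseline_clr_ua / 2
  synthesis <- ml_min_to_ml_h(baseline_clr_ua + clgut) *
    mg_dl_to_mg_ml(baseline_sua)   # mg/h
  structure(list(
    vd_ua = vd_ua, f_reabs = f_reabs, gfr = gfr, clgut_ua = clgut,
    synthesis_rate = synthesis,
    baseline_sua = baseline_sua, baseline_clr_ua = baseline_clr_ua
  ), class = "urate_physiology")
}

#' @export
print.urate_physiology <- function(x, ...) {
  cat("Urate physiology\n")
  cat(sprintf("  Vd_UA     = %.4g mL\n  f_reabs   = %.4g\n  GFR       = %.4g mL/min\n",
              x$vd_ua, x$f_reabs, x$gfr))
  cat(sprintf("  CLGut_UA  = %.4g mL/min\n  Synthesis = %.4g mg/h (%.4g mg/day)\n",
              x$clgut_ua, x$synthesis_rate, x$synthesis_rate * H_PER_DAY))
  cat(sprintf("  baseline SUA = %.3g mg/dL, baseline CLR_UA = %.3g mL/min\n",
              x$baseline_sua, x$baseline_clr_ua))
  invisible(x)
}

#' Emax drug-effect parameters
#'
#' Maximal fractional relief of tubular urate reabsorption and the total
#' plasma drug concentration producing half that effect.
#'
#' @param emax maximal effect, in `(0, 1]`
#' @param ec50 half-maximal total plasma concentration (ng/mL), > 0
#' @return an object of class `emax_params`
#' @export
emax_params <- function(emax, ec50) {
  stopifnot(emax > 0, emax <= 1, ec50 > 0)
  structure(list(emax = emax, ec50 = ec50), class = "emax_params")
}

#' Renal urate clearance from excreted amount and exposure
#'
#' `CLR_UA = Xu_UA / AUEC`, the interval-mean renal clearance implied by an
#' excreted amount and the area under the serum-urate curve over the same
#' interval, converted to mL/min.
#'
#' @param xu_ua urinary urate excreted over the interval (mg), >= 0
#' @param auec area under the SUA-time curve over the interval (mg*h/dL), > 0
#' @return clearance (mL/min)
#' @export
clearance_from_excretion <- function(xu_ua, auec) {
  if (auec <= 0) stop("auec must be > 0")
  stopifnot(xu_ua >= 0)
  (xu_ua / auec) * ML_PER_DL / MIN_PER_H
}

#' Baseline urate fluxes from pre-dose observations
#'
#' Applies the 2:1 renal:non-renal excretion closure to pre-dose data:
#' gut excretion `Xf_UA = Xu_UA / 2`, gut clearance `CLGut_UA = CLR_UA / 2`,
#' and production `Synthesis = Xu_UA + Xf_UA = 1.5 * Xu_UA`.
#'
#' @param xu_ua_baseline 24 h urinary urate excretion (mg/day), >= 0
#' @param clr_ua_baseline renal urate clearance (mL/min), >= 0
#' @return list with `xf_ua` (mg/day), `clgut_ua` (mL/min), `synthesis`
#'   (mg/day)
#' @export
derive_baseline <- function(xu_ua_baseline, clr_ua_baseline) {
  stopifnot(xu_ua_baseline >= 0, clr_ua_baseline >= 0)
  list(xf_ua = xu_ua_baseline / 2,
       clgut_ua = clr_ua_baseline / 2,
       synthesis = 1.5 * xu_ua_baseline)
}

#' Urate distribution volume from a delta mass balance
#'
#' `Vd_UA = (dXu_UA + dXf_UA) / dSUA`: the extra urate excreted over 24 h
#' (urinary increase plus the signed change in gut excretion) divided by the
#' 24 h fall in serum urate, which by conservation equals the pool volume.
#'
#' @param d_xu_ua increase in 24 h urinary urate vs baseline (mg)
#' @param d_xf_ua signed change in 24 h gut urate excretion vs baseline (mg)
#' @param d_sua magnitude of the SUA decrease over 24 h (mg/dL), > 0
#' @return distribution volume (mL)
#' @export
estimate_vd_ua <- function(d_xu_ua, d_xf_ua, d_sua) {
  if (d_sua <= 0) stop("d_sua must be > 0 (SUA must fall for the delta balance)")
  vd <- (d_xu_ua + d_xf_ua) / mg_dl_to_mg_ml(d_sua)
  if (vd < 0) {
    stop("inconsistent deltas: net excretion change and SUA change have opposite signs")
  }
  vd
}

#' Fractional tubular reabsorption from placebo clearance
#'
#' At baseline the renal route is filtration minus reabsorption:
#' `CLR_UA = GFR * (1 - f_reabs)`, so `f_reabs = 1 - CLR_UA / GFR`.
#'
#' @param clr_ua renal urate clearance (mL/min), in `[0, gfr]`
#' @param gfr glomerular filtration rate (mL/min), > 0
#' @return fraction in `[0, 1]`
#' @export
estimate_freabs <- function(clr_ua, gfr) {
  stopifnot(gfr > 0, clr_ua >= 0)
  if (clr_ua > gfr) {
    stop("clr_ua exceeds gfr: net tubular secretion is outside this model")
  }
  1 - clr_ua / gfr
}

#' GFR implied by a baseline clearance and reabsorption fraction
#'
#' Rearranges the baseline relation when no creatinine-clearance data are
#' available: `GFR = CLR_UA / (1 - f_reabs)`.
#'
#' @param clr_ua baseline renal urate clearance (mL/min), >= 0
#' @param f_reabs fractional reabsorption, < 1
#' @return GFR (mL/min)
#' @export
implied_gfr <- function(clr_ua, f_reabs) {
  if (f_reabs >= 1) stop("f_reabs must be < 1 to imply a finite GFR")
  stopifnot(clr_ua >= 0)
  clr_ua / (1 - f_reabs)
}

#' Fractional drug effect on reabsorption (Emax model)
#'
#' `E(Cp) = Emax * Cp / (EC50 + Cp)`: strictly increasing in `Cp`, zero at
#' zero, asymptote `Emax`.
#'
#' @param params an [emax_params()]
#' @param cp total plasma drug concentration (ng/mL), >= 0, vectorized
#' @return effect fraction in `[0, emax)`
#' @export
effect_fraction <- function(params, cp) {
  stopifnot(inherits(params, "emax_params"), all(cp >= 0))
  params$emax * cp / (params$ec50 + cp)
}

#' Renal urate clearance under drug
#'
#' Filtration minus the drug-attenuated reabsorption:
#' `CLR_UA(Cp) = GFR - f_reabs * GFR * (1 - E(Cp))`. Equals the baseline
#' clearance at `Cp = 0` and rises monotonically to
#' `GFR * (1 - f_reabs * (1 - Emax))` as `Cp` grows.
#'
#' @param phys a [urate_physiology()]
#' @param params an [emax_params()]
#' @param cp total plasma drug concentration (ng/mL), >= 0, vectorized
#' @return clearance (mL/min)
#' @export
renal_clearance <- function(phys, params, cp) {
  stopifnot(inherits(phys, "urate_physiology"))
  e <- effect_fraction(params, cp)
  phys$gfr - phys$f_reabs * phys$gfr * (1 - e)
}

#' Reference PD parameters for dotinurad
#'
#' Emax = 0.51, EC50 = 196 ng/mL (total plasma concentration), the estimates
#' from the first-in-human programme of dotinurad.
#'
#' @return an [emax_params()] object
#' @export
reference_emax_params <- function() emax_params(emax = 0.51, ec50 = 196)

#' Reference urate physiology for healthy adult men
#'
#' Baseline SUA 5.71 mg/dL, baseline renal urate clearance 7.10 mL/min,
#' urate distribution volume 16.0 L, fractional reabsorption 0.943, GFR
#' implied from the baseline relation (about 124.6 mL/min).
#'
#' @return a [urate_physiology()] object
#' @export
reference_physiology <- function() {
  urate_physiology(baseline_sua = 5.71, baseline_clr_ua = 7.10,
                   vd_ua = 16000, f_reabs = 0.943)
}
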