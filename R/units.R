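# Canonical units: time h; drug amount ng (mg doses converted here); drug
# volume mL; drug concentration ng/mL. Urate: amounts mg; SUA mg/dL stored,
# mg/mL inside mass-balance arithmetic; clearances mL/min stored, mL/h inside
# the mass balance. Every factor lives in this file and nowhere else.

NG_PER_MG <- 1e6
MIN_PER_H <- 60
ML_PER_DL <- 100
H_PER_DAY <- 24

#' Convert a dose in mg to ng
#' @param mg dose in milligrams
#' @return dose in nanograms
#' @export
mg_to_ng <- function(mg) mg * NG_PER_MG

#' Convert a clearance in mL/min to mL/h
#' @param ml_min clearance in mL/min
#' @return clearance in mL/h
#' @export
ml_min_to_ml_h <- function(ml_min) ml_min * MIN_PER_H

#' Convert a concentration in mg/dL to mg/mL
#' @param mg_dl concentration in mg/dL
#' @return concentration in mg/mL
#' @export
mg_dl_to_mg_ml <- function(mg_dl) mg_dl / ML_PER_DL

#' Convert a mass concentration in ng/mL to nmol/L
#'
#' ng/mL equals ug/L, so dividing by the molar mass in g/mol gives umol/L;
#' times 1000 gives nmol/L.
#'
#' @param ng_ml mass concentration (ng/mL)
#' @param mw molar mass (g/mol); defaults to dotinurad, 358.2 g/mol
#' @return molar concentration (nmol/L)
#' @export
ng_ml_to_nmol_l <- function(ng_ml, mw = DOTINURAD_MW) ng_ml / mw * 1000

#' Molar mass of dotinurad (g/mol)
#' @export
DOTINURAD_MW <- 358.2

#' Free (unbound) concentration from total concentration
#'
#' Only the unbound fraction of a highly protein-bound drug reaches the
#' luminal transporter it inhibits; this scales a total plasma concentration
#' by (1 - protein_binding).
#'
#' @param total total concentration (any unit)
#' @param protein_binding bound fraction in `[0, 1)`
#' @return free concentration in the same unit
#' @export
free_concentration <- function(total, protein_binding) {
  stopifnot(protein_binding >= 0, protein_binding < 1)
  total * (1 - protein_binding)
}

#' Weight-normalized distribution volume
#' @param vd_l distribution volume (L)
#' @param weight_kg body weight (kg)
#' @return L/kg
#' @export
vd_per_kg <- function(vd_l, weight_kg) {
  stopifnot(weight_kg > 0)
  vd_l / weight_kg
}
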