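#' Configuration for the synthetic study generator
#'
#' Population values default to the dotinurad reference estimates and the
#' healthy-volunteer baselines (SUA 5.71 mg/dL, urinary urate 575 mg/day,
#' renal urate clearance 7.10 mL/min). Between-subject variability is
#' lognormal with coefficients of variation taken from the printed
#' dispersions where available, otherwise 20%; residual error is
#' multiplicative lognormal (10% on plasma drug, 5% on SUA and urine
#' concentrations), a synthetic-data choice, not an estimate from any study.
#'
#' @param pop named list of population means: `v_f`, `ka`, `ke`, `sua0`,
#'   `clr0`, `vd_ua`, `f_reabs`, `emax`, `ec50`, `weight`
#' @param bsv named list of between-subject CVs (same names; 0 allowed)
#' @param residual named list of residual CVs: `plasma`, `sua`, `urine`
#' @param n_active,n_placebo cohort sizes (default 6 and 3)
#' @param sad_doses single doses (mg) for the SAD design
#' @param mad_doses once-daily doses (mg) for the MAD design
#' @param mad_days dosing days in the MAD design
#' @param loq_plasma lower limit of quantitation for plasma drug (ng/mL);
#'   values below are reported as 0 with a below-limit flag
#' @return a list of class `study_config`
#' @export
study_config <- function(
    pop = list(v_f = 10585, ka = 0.770, ke = 0.0795,
               sua0 = 5.71, clr0 = 7.10, vd_ua = 16000, f_reabs = 0.943,
               emax = 0.51, ec50 = 196, weight = 60),
    bsv = list(v_f = 0.072, ka = 0.142, ke = 0.093,
               sua0 = 0.75 / 5.71, clr0 = 1.51 / 7.10,
               vd_ua = 0.366, f_reabs = 0.006,
               emax = 0.046, ec50 = 0.119, weight = 0.10),
    residual = list(plasma = 0.10, sua = 0.05, urine = 0.05),
    n_active = 6, n_placebo = 3,
    sad_doses = c(0.5, 1, 2, 5, 10, 20),
    mad_doses = c(2, 5), mad_days = 7,
    loq_plasma = 1) {
  if (any(unlist(bsv) < 0) || any(unlist(residual) < 0)) {
    stop("coefficients of variation must be >= 0")
  }
  structure(list(pop = pop, bsv = bsv, residual = residual,
                 n_active = n_active, n_placebo = n_placebo,
                 sad_doses = sad_doses, mad_doses = mad_doses,
                 mad_days = mad_days, loq_plasma = loq_plasma),
            class = "study_config")
}

# mean-preserving lognormal draw: E[X] = mu for any cv
rlnorm_cv <- function(n, mu, cv) {
  if (cv == 0) return(rep(mu, n))
  s <- sqrt(log(1 + cv^2))
  mu * exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Draw one synthetic subject
#'
#' Samples per-subject PK, PD and physiology parameters around the
#' population values with lognormal between-subject variability, closing the
#' physiology invariants (2:1 excretion split, baseline steady state).
#' Deterministic for a given seed. Weight is truncated to the 50-80 kg
#' healthy adult male range and body surface area follows Du Bois at a fixed
#' 1.70 m height.
#'
#' @param config a [study_config()]
#' @param seed integer seed
#' @param subject_id label
#' @return a list of class `subject_record`: `subject_id`, `weight`, `bsa`,
#'   `true_pk` ([pk_params()]), `true_phys` ([urate_physiology()]),
#'   `true_pd` ([emax_params()])
#' @export
generate_subject <- function(config, seed, subject_id = "S01") {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  p <- config$pop; b <- config$bsv
  draw <- function(name) rlnorm_cv(1, p[[name]], b[[name]])
  weight <- min(max(draw("weight"), 50), 80)
  bsa <- 0.007184 * weight^0.425 * 170^0.725          # Du Bois, height 170 cm
  pk <- pk_params(v_f = draw("v_f"), ka = draw("ka"), ke = draw("ke"))
  f_reabs <- min(draw("f_reabs"), 0.999)
  phys <- urate_physiology(baseline_sua = draw("sua0"),
                           baseline_clr_ua = draw("clr0"),
                           vd_ua = draw("vd_ua"), f_reabs = f_reabs)
  pd <- emax_params(emax = min(draw("emax"), 1), ec50 = draw("ec50"))
  structure(list(subject_id = subject_id, weight = weight, bsa = bsa,
                 true_pk = pk, true_phys = phys, true_pd = pd),
            class = "subject_record")
}

#' Multiplicative lognormal measurement noise
#'
#' Mean-preserving, independent across records, deterministic given the
#' seed. `cv = 0` is the identity.
#'
#' @param x non-negative values
#' @param cv residual coefficient of variation, >= 0
#' @param seed integer seed
#' @return noised values
#' @export
add_noise <- function(x, cv, seed) {
  if (cv < 0) stop("cv must be >= 0")
  if (any(x < 0, na.rm = TRUE)) stop("upstream data error: negative concentrations")
  if (cv == 0) return(x)
  set.seed(seed)
  s <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), -s^2 / 2, s))
}

# simulate one subject under a regimen; returns plasma/sua/urine tables
simulate_subject_tables <- function(subj, dose, regimen, blood_times,
                                    urine_windows, config, seed, fed = 0L) {
  active <- dose > 0
  phys <- subj$true_phys
  horizon <- max(c(blood_times, vapply(urine_windows, max, 0)))
  course <- simulate_sua(phys, subj$true_pd, subj$true_pk, regimen,
                         sim_config(dt = 1, horizon = horizon,
                                    record_intervals = urine_windows))

  cp <- if (active) pk_concentration(subj$true_pk, regimen, blood_times) else
    numeric(length(blood_times))
  cp <- add_noise(cp, config$residual$plasma, seed)
  bloq <- cp < config$loq_plasma & blood_times > 0
  cp[bloq] <- 0
  plasma <- data.frame(subject_id = subj$subject_id, dose_mg = dose,
                       time_h = blood_times, conc_ng_ml = cp,
                       bloq = as.integer(bloq), fed = fed,
                       day = blood_times %/% 24)

  sua <- stats::approx(course$times, course$sua, xout = blood_times)$y
  sua <- add_noise(sua, config$residual$sua, seed + 1L)
  sua_tab <- data.frame(subject_id = subj$subject_id, dose_mg = dose,
                        time_h = blood_times, sua_mg_dl = sua,
                        screat_mg_dl = 0.9)

  iv <- course$intervals
  width <- iv$t_end - iv$t_start
  volume <- 1500 * width / 24                           # mL, 1.5 L/day
  xu <- add_noise(iv$xu_mg, config$residual$urine, seed + 2L)
  # urinary creatinine set so BSA-normalized creatinine clearance = true GFR
  creat_mg <- phys$gfr * subj$bsa / 1.73 *
    mg_dl_to_mg_ml(0.9) * MIN_PER_H * width
  urine <- data.frame(subject_id = subj$subject_id, dose_mg = dose,
                      t_start_h = iv$t_start, t_end_h = iv$t_end,
                      volume_ml = volume,
                      urate_mg_dl = xu / volume * ML_PER_DL,
                      creat_mg_dl = creat_mg / volume * ML_PER_DL,
                      drug_ng_ml = NA_real_)
  list(plasma = plasma, sua = sua_tab, urine = urine)
}

truth_row <- function(subj, arm, dose, fed = 0L) {
  data.frame(subject_id = subj$subject_id, arm = arm, dose_mg = dose,
             fed = fed, weight_kg = subj$weight, bsa_m2 = subj$bsa,
             v_f = subj$true_pk$v_f, ka = subj$true_pk$ka, ke = subj$true_pk$ke,
             sua0 = subj$true_phys$baseline_sua,
             clr0 = subj$true_phys$baseline_clr_ua,
             vd_ua = subj$true_phys$vd_ua, f_reabs = subj$true_phys$f_reabs,
             gfr = subj$true_phys$gfr,
             emax = subj$true_pd$emax, ec50 = subj$true_pd$ec50)
}

generate_design <- function(config, seed, doses, design, regimen_for,
                            blood_times, urine_windows) {
  plasma <- sua <- urine <- truth <- list()
  k <- 0L
  for (dose in doses) {
    for (i in seq_len(config$n_active + config$n_placebo)) {
      k <- k + 1L
      active <- i <= config$n_active
      id <- sprintf("%s-%03d", design, k)
      subj <- generate_subject(config, seed = seed + 10L * k, subject_id = id)
      d <- if (active) dose else 0
      tabs <- simulate_subject_tables(
        subj, d, regimen_for(d), blood_times, urine_windows,
        config, seed = seed + 10L * k + 5L)
      plasma[[k]] <- tabs$plasma; sua[[k]] <- tabs$sua; urine[[k]] <- tabs$urine
      truth[[k]] <- truth_row(subj, arm = if (active) paste0(dose, " mg") else "placebo",
                              dose = d)
    }
  }
  truth <- do.call(rbind, truth)
  structure(list(design = design, seed = seed,
                 plasma = do.call(rbind, plasma),
                 sua = do.call(rbind, sua),
                 urine = do.call(rbind, urine),
                 demog = truth[c("subject_id", "arm", "dose_mg", "fed",
                                 "weight_kg", "bsa_m2")],
                 truth = truth),
            class = "study_dataset")
}

#' Generate a synthetic single-ascending-dose study
#'
#' Six single-dose cohorts (0.5-20 mg by default), each with 6 active and 3
#' placebo subjects, blood at the standard 0-48 h schedule and urine in the
#' baseline plus 0-6, 6-12, 12-24, 24-36 and 36-48 h windows. Plasma comes
#' from each subject's one-compartment parameters, SUA and urinary urate
#' from a per-subject forward simulation, all with the configured residual
#' noise and the 1 ng/mL plasma quantitation floor.
#'
#' @param config a [study_config()]
#' @param seed integer seed; identical (config, seed) regenerate the dataset
#'   exactly
#' @return a `study_dataset`: tables `plasma`, `sua`, `urine`, `truth`
#' @export
generate_sad <- function(config = study_config(), seed = 1L) {
  generate_design(config, seed, config$sad_doses, "SAD",
                  regimen_for = function(d) dose_regimen(dose = d, n_doses = 1),
                  blood_times = sad_blood_times(),
                  urine_windows = sad_urine_windows())
}

#' Generate a synthetic multiple-ascending-dose study
#'
#' Once-daily cohorts (2 and 5 mg by default, 7 days), blood at the
#' multiple-dose schedule and 24 h urine collections from the pre-dose day
#' to 72 h after the last dose.
#'
#' @inheritParams generate_sad
#' @return a `study_dataset`
#' @export
generate_mad <- function(config = study_config(), seed = 1L) {
  days <- config$mad_days
  horizon <- (days - 1) * 24 + 72
  windows <- lapply(seq(-24, horizon - 24, by = 24), function(s) c(s, s + 24))
  generate_design(config, seed + 1000L, config$mad_doses, "MAD",
                  regimen_for = function(d) dose_regimen(dose = d, interval = 24,
                                                         n_doses = days),
                  blood_times = mad_blood_times(days),
                  urine_windows = windows)
}
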