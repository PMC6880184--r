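#' End-to-end pipeline: fit the SAD study, predict the MAD study
#'
#' Executes the full estimation cascade on a single-ascending-dose dataset
#' and confirms the model against a multiple-ascending-dose dataset:
#' per-subject one-compartment PK fits (pooled by arithmetic mean), NCA per
#' dose, the dose-proportionality power model, baseline urate fluxes,
#' urate distribution volume by delta mass balance, fractional reabsorption
#' from the placebo arms, the Emax fit on pooled interval means, and the
#' forward SUA prediction at each MAD dose with bias/RMSE against the
#' observed values.
#'
#' Subjects whose plasma data are uninformative (e.g. placebo) are excluded
#' from the PK stages; a stage that cannot run records a stage-labeled
#' diagnostic in `errors` and the remaining stages still execute.
#'
#' @param sad a SAD `study_dataset` (tables `plasma`, `sua`, `urine`, and
#'   `demog` or `truth` for body surface area)
#' @param mad optional MAD `study_dataset` for model confirmation
#' @param n_placebo_freabs number of placebo subjects used for the
#'   reabsorption estimate (default all)
#' @return an object of class `pipeline_report`: `pk` (pooled
#'   [pk_params()]), `pk_cv_percent`, `nca_by_dose`, `dose_proportionality`
#'   (slopes for Cmax and AUC), `baseline` (SUA, Xu, CLR means),
#'   `vd_ua_ml` (+ per-dose means), `f_reabs`, `gfr_ml_min`, `pd`
#'   ([emax_params()]), `effect_points`, `mad_comparison`, `errors`
#' @export
run_pipeline <- function(sad, mad = NULL, n_placebo_freabs = NULL) {
  stopifnot(inherits(sad, "study_dataset"))
  errors <- character(0)
  note <- function(stage, e) {
    errors <<- c(errors, sprintf("stage %s: %s", stage, conditionMessage(e)))
    NULL
  }

  demog <- sad$demog %||% sad$truth
  subjects <- unique(sad$plasma$subject_id)
  dose_of <- function(id) sad$plasma$dose_mg[sad$plasma$subject_id == id][1]
  doses <- vapply(subjects, dose_of, numeric(1))
  active <- subjects[doses > 0]
  placebo <- subjects[doses == 0]

  sub_tabs <- function(id) {
    list(plasma = sad$plasma[sad$plasma$subject_id == id, ],
         sua = sad$sua[sad$sua$subject_id == id, ],
         urine = sad$urine[sad$urine$subject_id == id, ])
  }

  ## --- PK stages -----------------------------------------------------
  pk_fits <- NULL
  pk_pooled <- pk_cv <- NULL
  tryCatch({
    if (length(active) == 0) stop("uninformative data: no active-dose subjects")
    pk_fits <- lapply(active, function(id) {
      tb <- sub_tabs(id)
      pl <- tb$plasma[!(tb$plasma$bloq %||% 0), ]
      prof <- plasma_profile(id, pl$time_h, pl$conc_ng_ml,
                             dose_regimen(dose = pl$dose_mg[1]))
      fit_pk(prof)
    })
    m <- sapply(pk_fits, function(f) c(f$v_f, f$ka, f$ke))
    pk_pooled <- pk_params(v_f = mean(m[1, ]), ka = mean(m[2, ]), ke = mean(m[3, ]))
    pk_cv <- rowMeans(sapply(pk_fits, function(f) attr(f, "cv_percent")))
  }, error = function(e) note("fit_pk", e))

  nca_by_dose <- tryCatch({
    if (length(active) == 0) stop("uninformative data: no active-dose subjects")
    rows <- lapply(active, function(id) {
      tb <- sub_tabs(id)
      pl <- tb$plasma[!(tb$plasma$bloq %||% 0), ]
      prof <- plasma_profile(id, pl$time_h, pl$conc_ng_ml,
                             dose_regimen(dose = pl$dose_mg[1]))
      r <- nca(prof)
      data.frame(subject_id = id, dose_mg = pl$dose_mg[1], cmax = r$cmax,
                 tmax = r$tmax, auc_0_24 = r$auc_0_24, auc_0_inf = r$auc_0_inf,
                 t_half = r$t_half, cl_f = r$cl_f)
    })
    per_subject <- do.call(rbind, rows)
    agg <- stats::aggregate(per_subject[c("cmax", "tmax", "auc_0_24",
                                          "auc_0_inf", "t_half", "cl_f")],
                            by = list(dose_mg = per_subject$dose_mg), FUN = mean)
    attr(agg, "per_subject") <- per_subject
    agg
  }, error = function(e) note("nca", e))

  dp <- tryCatch({
    ps <- attr(nca_by_dose, "per_subject")
    if (is.null(ps)) stop("uninformative data: NCA unavailable")
    list(cmax = dose_proportionality(ps$dose_mg, ps$cmax),
         auc = dose_proportionality(ps$dose_mg, ps$auc_0_inf))
  }, error = function(e) note("dose_proportionality", e))

  ## --- baseline PD stages -------------------------------------------
  base_of <- function(id) {
    tb <- sub_tabs(id)
    sua0 <- tb$sua$sua_mg_dl[tb$sua$time_h == 0][1]
    ur0 <- tb$urine[tb$urine$t_start_h == -24 & tb$urine$t_end_h == 0, ]
    xu0 <- ur0$urate_mg_dl / ML_PER_DL * ur0$volume_ml
    clr0 <- clearance_from_excretion(xu0, sua0 * 24)
    gfr <- subject_gfr(ur0, tb$sua, demog, id)
    list(sua0 = sua0, xu0 = xu0, clr0 = clr0, gfr = gfr, tb = tb)
  }

  baseline <- tryCatch({
    bs <- lapply(subjects, base_of)
    data.frame(subject_id = subjects, dose_mg = doses,
               sua0 = vapply(bs, `[[`, 0, "sua0"),
               xu0 = vapply(bs, `[[`, 0, "xu0"),
               clr0 = vapply(bs, `[[`, 0, "clr0"),
               gfr = vapply(bs, `[[`, 0, "gfr"))
  }, error = function(e) note("baseline", e))

  fluxes <- if (!is.null(baseline)) {
    derive_baseline(mean(baseline$xu0), mean(baseline$clr0))
  }

  f_reabs <- tryCatch({
    pb <- baseline[baseline$dose_mg == 0, ]
    if (!is.null(n_placebo_freabs)) pb <- utils::head(pb, n_placebo_freabs)
    if (nrow(pb) == 0) stop("no placebo subjects for the reabsorption estimate")
    pf <- mapply(function(id) {
      tb <- sub_tabs(id)
      w24 <- tb$urine[tb$urine$t_start_h >= 0 & tb$urine$t_end_h <= 24, ]
      xu <- sum(w24$urate_mg_dl / ML_PER_DL * w24$volume_ml)
      auec <- trapz_window(tb$sua$time_h, tb$sua$sua_mg_dl, 0, 24)
      estimate_freabs(clearance_from_excretion(xu, auec),
                      baseline$gfr[baseline$subject_id == id])
    }, pb$subject_id)
    mean(pf)
  }, error = function(e) note("estimate_freabs", e))

  vd <- tryCatch({
    act <- baseline[baseline$dose_mg > 0, ]
    if (nrow(act) == 0) stop("uninformative data: no dosed subjects for the delta balance")
    per <- mapply(function(id) {
      tb <- sub_tabs(id)
      b <- baseline[baseline$subject_id == id, ]
      w24 <- tb$urine[tb$urine$t_start_h >= 0 & tb$urine$t_end_h <= 24, ]
      xu24 <- sum(w24$urate_mg_dl / ML_PER_DL * w24$volume_ml)
      auec24 <- trapz_window(tb$sua$time_h, tb$sua$sua_mg_dl, 0, 24)
      clgut <- b$clr0 / 2
      d_xu <- xu24 - b$xu0
      d_xf <- clgut * (auec24 - b$sua0 * 24) / ML_PER_DL * MIN_PER_H
      sua24 <- tb$sua$sua_mg_dl[tb$sua$time_h == 24][1]
      estimate_vd_ua(d_xu, d_xf, b$sua0 - sua24)
    }, act$subject_id)
    by_dose <- tapply(per, act$dose_mg, mean)
    list(mean_ml = mean(per), by_dose_ml = by_dose, n = length(per))
  }, error = function(e) note("estimate_vd_ua", e))

  pd_fit <- effect_points <- NULL
  tryCatch({
    if (length(active) == 0) stop("uninformative data: no active-dose subjects")
    if (is.null(f_reabs)) stop("reabsorption estimate unavailable")
    pts <- lapply(active, function(id) {
      b <- baseline[baseline$subject_id == id, ]
      tb <- sub_tabs(id)
      phys <- urate_physiology(baseline_sua = b$sua0,
                               baseline_clr_ua = b$gfr * (1 - f_reabs),
                               vd_ua = 16000, f_reabs = f_reabs, gfr = b$gfr)
      ur <- tb$urine[tb$urine$t_start_h >= 0, ]
      ur <- data.frame(t_start = ur$t_start_h, t_end = ur$t_end_h,
                       xu_mg = ur$urate_mg_dl / ML_PER_DL * ur$volume_ml)
      im <- interval_means(tb$plasma$time_h, tb$plasma$conc_ng_ml, ur,
                           tb$sua$time_h, tb$sua$sua_mg_dl, phys)
      cbind(subject_id = id, dose_mg = b$dose_mg, im)
    })
    effect_points <- do.call(rbind, pts)
    pd_fit <- fit_emax(effect_points$cp_mean, effect_points$effect)
  }, error = function(e) note("fit_emax", e))

  ## --- MAD confirmation ----------------------------------------------
  mad_cmp <- tryCatch({
    if (is.null(mad)) NULL else {
      if (is.null(pk_pooled) || is.null(pd_fit)) {
        stop("PK or PD estimates unavailable for prediction")
      }
      phys_hat <- urate_physiology(
        baseline_sua = mean(baseline$sua0),
        baseline_clr_ua = mean(baseline$gfr) * (1 - f_reabs),
        vd_ua = vd$mean_ml, f_reabs = f_reabs, gfr = mean(baseline$gfr))
      rows <- lapply(sort(unique(mad$plasma$dose_mg[mad$plasma$dose_mg > 0])),
        function(d) {
          pred <- predict_mad(phys_hat, pd_fit, pk_pooled, dose = d)
          ids <- unique(mad$sua$subject_id[mad$sua$dose_mg == d])
          obs <- mad$sua[mad$sua$subject_id %in% ids, ]
          obs_mean <- stats::aggregate(sua_mg_dl ~ time_h, data = obs, FUN = mean)
          m <- merge(obs_mean, pred$samples[c("time_h", "sua_mg_dl")],
                     by = "time_h", suffixes = c("_obs", "_pred"))
          data.frame(dose_mg = d, time_h = m$time_h,
                     sua_obs = m$sua_mg_dl_obs, sua_pred = m$sua_mg_dl_pred)
        })
      do.call(rbind, rows)
    }
  }, error = function(e) note("predict_mad", e))

  mad_summary <- if (!is.null(mad_cmp)) {
    err <- mad_cmp$sua_pred - mad_cmp$sua_obs
    list(bias_mg_dl = mean(err), rmse_mg_dl = sqrt(mean(err^2)))
  }

  structure(list(
    pk = pk_pooled, pk_cv_percent = pk_cv,
    nca_by_dose = nca_by_dose, dose_proportionality = dp,
    baseline = if (!is.null(baseline)) {
      list(sua_mg_dl = mean(baseline$sua0), xu_mg_day = mean(baseline$xu0),
           clr_ua_ml_min = mean(baseline$clr0), gfr_ml_min = mean(baseline$gfr))
    },
    baseline_fluxes = fluxes,
    vd_ua = vd, f_reabs = f_reabs,
    pd = pd_fit,
    pd_cv_percent = if (!is.null(pd_fit)) attr(pd_fit, "cv_percent"),
    effect_points = effect_points,
    mad_comparison = mad_cmp, mad_summary = mad_summary,
    n_subjects = length(subjects), errors = errors
  ), class = "pipeline_report")
}

# BSA-normalized creatinine clearance from the baseline urine collection;
# falls back to NA when creatinine or demographics are missing
subject_gfr <- function(urine_base, sua_tab, demog, id) {
  if (is.null(urine_base$creat_mg_dl) || is.null(demog) ||
      !"bsa_m2" %in% names(demog)) {
    return(NA_real_)
  }
  scr <- sua_tab$screat_mg_dl[1] %||% 0.9
  bsa <- demog$bsa_m2[demog$subject_id == id][1]
  width_min <- (urine_base$t_end_h - urine_base$t_start_h) * MIN_PER_H
  ccr <- (urine_base$creat_mg_dl / ML_PER_DL * urine_base$volume_ml) /
    (mg_dl_to_mg_ml(scr) * width_min)
  ccr * 1.73 / bsa
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("PK/PD pipeline report\n")
  if (!is.null(x$pk)) {
    cat(sprintf("  PK (pooled): V/F = %.4g mL, Ka = %.4g /h, Ke = %.4g /h\n",
                x$pk$v_f, x$pk$ka, x$pk$ke))
  }
  if (!is.null(x$vd_ua)) {
    cat(sprintf("  Vd_UA = %.3g L (n = %d)\n", x$vd_ua$mean_ml / 1000, x$vd_ua$n))
  }
  if (!is.null(x$f_reabs)) cat(sprintf("  f_reabs = %.4g\n", x$f_reabs))
  if (!is.null(x$pd)) {
    cat(sprintf("  Emax = %.3g, EC50 = %.4g ng/mL\n", x$pd$emax, x$pd$ec50))
  }
  if (!is.null(x$mad_summary)) {
    cat(sprintf("  MAD prediction: bias %.3g, RMSE %.3g mg/dL\n",
                x$mad_summary$bias_mg_dl, x$mad_summary$rmse_mg_dl))
  }
  if (length(x$errors) > 0) cat("  errors:\n", paste("   -", x$errors, collapse = "\n"), "\n")
  invisible(x)
}
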