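# Table I/O with strict schema validation. Unknown columns are preserved
# with a warning; missing required columns or non-monotone per-subject times
# are errors naming the offending rows.

plasma_schema <- c("subject_id", "dose_mg", "time_h", "conc_ng_ml")
sua_schema <- c("subject_id", "dose_mg", "time_h", "sua_mg_dl")
urine_schema <- c("subject_id", "dose_mg", "t_start_h", "t_end_h",
                  "volume_ml", "urate_mg_dl")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table: missing required column(s) %s",
                 what, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(required, "bloq", "fed", "day",
                                "creat_mg_dl", "drug_ng_ml", "screat_mg_dl"))
  if (length(extra) > 0) {
    warning(sprintf("%s table: unknown column(s) %s preserved",
                    what, paste(extra, collapse = ", ")))
  }
  df
}

check_monotone_times <- function(df, time_col, what) {
  bad <- unlist(lapply(split(df, df$subject_id), function(d) {
    t <- d[[time_col]]
    if (any(diff(t) <= 0)) d$subject_id[1] else NULL
  }))
  if (length(bad) > 0) {
    stop(sprintf("%s table: times not strictly increasing for subject(s) %s",
                 what, paste(bad, collapse = ", ")))
  }
  df
}

#' Read and validate a plasma concentration table
#' @param path CSV with columns `subject_id`, `dose_mg`, `time_h`,
#'   `conc_ng_ml` (plus optional `bloq`, `fed`, `day`)
#' @return validated data frame
#' @export
read_plasma <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_monotone_times(check_schema(df, plasma_schema, "plasma"),
                       "time_h", "plasma")
}

#' Read and validate a serum urate table
#' @param path CSV with columns `subject_id`, `dose_mg`, `time_h`,
#'   `sua_mg_dl` (plus optional `screat_mg_dl`)
#' @return validated data frame
#' @export
read_sua <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_monotone_times(check_schema(df, sua_schema, "sua"), "time_h", "sua")
}

#' Read and validate an interval urine table
#' @param path CSV with columns `subject_id`, `dose_mg`, `t_start_h`,
#'   `t_end_h`, `volume_ml`, `urate_mg_dl` (plus optional `creat_mg_dl`,
#'   `drug_ng_ml`)
#' @return validated data frame
#' @export
read_urine <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, urine_schema, "urine")
  for (nm in c("creat_mg_dl", "drug_ng_ml")) {
    if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
  }
  if (any(df$t_end_h <= df$t_start_h)) {
    stop("urine table: t_end_h must exceed t_start_h in every row")
  }
  df
}

#' Write a study dataset's tables to CSV
#'
#' Emits `plasma.csv`, `sua.csv`, `urine.csv` and `truth.csv`; a
#' write-then-read round trip reproduces the tables.
#'
#' @param dataset a `study_dataset` from [generate_sad()] or [generate_mad()]
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(c("plasma", "sua", "urine", "truth"), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(dataset[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a study dataset written by [write_dataset()]
#' @param dir directory containing the CSVs
#' @param design design label, `"SAD"` or `"MAD"`
#' @return a `study_dataset`
#' @export
read_dataset <- function(dir, design = "SAD") {
  truth_path <- file.path(dir, "truth.csv")
  structure(list(
    design = design, seed = NA_integer_,
    plasma = read_plasma(file.path(dir, "plasma.csv")),
    sua = read_sua(file.path(dir, "sua.csv")),
    urine = read_urine(file.path(dir, "urine.csv")),
    truth = if (file.exists(truth_path))
      utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  ), class = "study_dataset")
}

#' Write a pipeline report to disk
#'
#' `report.json` holds the fitted parameters, diagnostics and provenance;
#' `nca.csv` and `effect_points.csv` hold the per-dose NCA summary and the
#' pooled effect points.
#'
#' @param report a `pipeline_report` from [run_pipeline()]
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalarize <- report[setdiff(names(report), c("nca_by_dose", "effect_points",
                                               "mad_comparison"))]
  jsonlite::write_json(scalarize, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(report$nca_by_dose)) {
    utils::write.csv(report$nca_by_dose, file.path(dir, "nca.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$effect_points)) {
    utils::write.csv(report$effect_points, file.path(dir, "effect_points.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$mad_comparison)) {
    utils::write.csv(report$mad_comparison, file.path(dir, "mad_comparison.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
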