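#' Round half up to a fixed number of decimals
#'
#' Display rounding for the report tables (0.05 rounds to 0.1), as opposed to
#' R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Per-patient RMSE summary of one run
#'
#' Computes the two headline metrics: the RMSE pooled over every test
#' prediction of the run ("total days"), and the RMSE restricted to
#' predictions whose target timestamp falls inside a physical-activity
#' interval. With no PA-flagged predictions the PA RMSE is undefined (`NA`),
#' never zero.
#'
#' @param run A `run_result` from [run_offline()] / [run_online()].
#' @param pa_type The patient's activity type (`"aerobic"`, `"anaerobic"`, or
#'   `NA`), carried into the summary for stratified averaging.
#' @return One-row data frame: `patient_id`, `config`, `pa_type`,
#'   `rmse_total_days`, `rmse_pa`, `n_predictions_total`, `n_predictions_pa`.
#' @export
summarize_run <- function(run, pa_type = NA_character_) {
  recs <- run$records
  if (is.null(recs) || nrow(recs) == 0L) {
    stop("summarize_run(): run contains no predictions", call. = FALSE)
  }
  e <- error_series(recs$truth, recs$prediction)
  pa <- recs$pa_flag
  data.frame(patient_id = run$patient_id, config = run$config,
             pa_type = pa_type,
             rmse_total_days = rmse(e),
             rmse_pa = if (any(pa)) rmse(e[pa]) else NA_real_,
             n_predictions_total = length(e),
             n_predictions_pa = sum(pa),
             stringsAsFactors = FALSE)
}

#' Cohort averages of per-patient RMSEs
#'
#' Unweighted means of the per-patient RMSEs: over all patients for the
#' total-days and PA columns, and within each activity-type stratum for the
#' PA column. Patients whose PA RMSE is undefined are dropped from the PA
#' averages.
#'
#' @param summaries Data frame of [summarize_run()] rows (one per patient).
#' @return List with `patients` (the input), `average` (one-row data frame
#'   with `rmse_total_days` and `rmse_pa`), and `by_type` (mean PA RMSE per
#'   activity type).
#' @export
aggregate_cohort <- function(summaries) {
  if (NROW(summaries) == 0L) stop("aggregate_cohort(): empty cohort", call. = FALSE)
  avg <- data.frame(
    rmse_total_days = mean(summaries$rmse_total_days),
    rmse_pa = mean(summaries$rmse_pa, na.rm = TRUE))
  strata <- summaries[!is.na(summaries$pa_type) & !is.na(summaries$rmse_pa), ]
  by_type <- if (nrow(strata) > 0L) {
    stats::aggregate(rmse_pa ~ pa_type, data = strata, FUN = mean)
  } else {
    data.frame(pa_type = character(0), rmse_pa = numeric(0))
  }
  list(patients = summaries, average = avg, by_type = by_type)
}

#' Side-by-side comparison table of the three configurations
#'
#' Builds the standard report: one row per patient with the total-days and
#' PA RMSEs of the offline, online, and online-with-penalty runs, followed by
#' the cohort average row and per-activity-type average rows (PA columns
#' only). Values are rounded half-up to one decimal for display; the
#' unrounded table is attached as attribute `"unrounded"`.
#'
#' @param offline,online,online_penalty Data frames of [summarize_run()] rows
#'   (one per patient, same patient set in the same order of ids).
#' @return Data frame with columns `patient_id`, `pa_type`,
#'   `total_offline`, `total_online`, `total_online_penalty`,
#'   `pa_offline`, `pa_online`, `pa_online_penalty`.
#' @export
render_comparison <- function(offline, online, online_penalty) {
  o <- offline[order(offline$patient_id), , drop = FALSE]
  n <- online[order(online$patient_id), , drop = FALSE]
  p <- online_penalty[order(online_penalty$patient_id), , drop = FALSE]
  if (!identical(o$patient_id, n$patient_id) ||
      !identical(o$patient_id, p$patient_id)) {
    stop("render_comparison(): the three summaries cover different patients",
         call. = FALSE)
  }
  tab <- data.frame(patient_id = o$patient_id, pa_type = o$pa_type,
                    total_offline = o$rmse_total_days,
                    total_online = n$rmse_total_days,
                    total_online_penalty = p$rmse_total_days,
                    pa_offline = o$rmse_pa,
                    pa_online = n$rmse_pa,
                    pa_online_penalty = p$rmse_pa,
                    stringsAsFactors = FALSE)
  avg_row <- function(label, rows, pa_only = FALSE) {
    data.frame(patient_id = label, pa_type = NA_character_,
               total_offline = if (pa_only) NA_real_ else mean(rows$total_offline),
               total_online = if (pa_only) NA_real_ else mean(rows$total_online),
               total_online_penalty = if (pa_only) NA_real_ else
                 mean(rows$total_online_penalty),
               pa_offline = mean(rows$pa_offline, na.rm = TRUE),
               pa_online = mean(rows$pa_online, na.rm = TRUE),
               pa_online_penalty = mean(rows$pa_online_penalty, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(tab, avg_row("Average RMSE", tab))
  for (ty in c("anaerobic", "aerobic")) {
    rows <- tab[!is.na(tab$pa_type) & tab$pa_type == ty, , drop = FALSE]
    if (nrow(rows) > 0L) {
      out <- rbind(out, avg_row(paste0("Average RMSE - ",
                                       toupper(substr(ty, 1L, 2L))),
                                rows, pa_only = TRUE))
    }
  }
  rounded <- out
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], round_half_up, digits = 1L)
  attr(rounded, "unrounded") <- out
  rownames(rounded) <- NULL
  rounded
}
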