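#' Summarize one scenario across subjects
#'
#' Sums usable and total minutes over subjects, computes the usable
#' percentage rounded to two decimals (the study's reporting convention),
#' and averages the subject-level SNRs.
#'
#' @param results Tibble with one row per subject:
#'   `subject_id`, `usable_minutes`, `total_minutes` and optionally `snr_db`.
#' @param scenario Scenario name attached to the summary.
#' @return One-row tibble: `scenario`, `n_subjects`, `total_minutes`,
#'   `usable_minutes`, `usable_pct`, `mean_snr_db`, `snr_db` (list column of
#'   the per-subject values).
#' @export
#' @examples
#' summarize_scenario(
#'   tibble::tibble(
#'     subject_id = c("a", "b"), usable_minutes = c(30, 23),
#'     total_minutes = c(47.5, 47.5)
#'   ),
#'   scenario = "city"
#' )
summarize_scenario <- function(results,
                               scenario = if ("scenario" %in% names(results)) {
                                 results$scenario[1]
                               } else {
                                 NA_character_
                               }) {
  if (nrow(results) < 1) abort("At least one subject is required.")
  usable <- sum(results$usable_minutes)
  total <- sum(results$total_minutes)
  snr <- if ("snr_db" %in% names(results)) results$snr_db else numeric(0)
  tibble(
    scenario = scenario,
    n_subjects = nrow(results),
    total_minutes = total,
    usable_minutes = usable,
    usable_pct = round(100 * usable / total, 2),
    mean_snr_db = if (length(snr)) mean(snr) else NA_real_,
    snr_db = list(snr)
  )
}

#' Study-level headline numbers
#'
#' The headline driving percentage is the unweighted mean of the three
#' driving scenarios' rounded usable percentages (city, highway, rural;
#' rest is excluded because it is not driving time), itself rounded to two
#' decimals. `daily_usable_minutes` scales that percentage to an assumed
#' daily driving time.
#'
#' @param scenario_summaries Row-bound [summarize_scenario()] outputs
#'   including the three driving scenarios.
#' @param daily_driving_min Assumed daily driving time, minutes.
#' @return One-row tibble: `driving_mean_usable_pct`, `daily_usable_minutes`,
#'   plus pooled minute totals across the driving scenarios.
#' @export
summarize_study <- function(scenario_summaries, daily_driving_min = 30) {
  driving <- filter(scenario_summaries, .data$scenario != "rest")
  need <- setdiff(c("city", "highway", "rural"), driving$scenario)
  if (length(need)) {
    abort(paste0("Missing driving scenario summaries: ", paste(need, collapse = ", ")))
  }
  pct <- round(mean(driving$usable_pct), 2)
  tibble(
    driving_mean_usable_pct = pct,
    daily_usable_minutes = pct / 100 * daily_driving_min,
    driving_usable_minutes = sum(driving$usable_minutes),
    driving_total_minutes = sum(driving$total_minutes)
  )
}

#' Long-format SNR table for distribution plots
#'
#' @param scenario_summaries Row-bound [summarize_scenario()] outputs with
#'   per-subject SNR lists and, optionally, `subject_id` lists; or a tibble
#'   already holding `subject_id`, `scenario`, `snr_db` columns.
#' @return Tibble `subject_id`, `scenario`, `snr_db`, one row per
#'   subject-scenario pair, values passed through unmodified.
#' @export
export_snr_distribution <- function(scenario_summaries) {
  if (!"snr_db" %in% names(scenario_summaries)) {
    abort("`scenario_summaries` must carry an `snr_db` column.")
  }
  if (!is.list(scenario_summaries$snr_db)) {
    return(select(
      scenario_summaries, any_of("subject_id"), "scenario", "snr_db"
    ))
  }
  scenario_summaries |>
    select("scenario", "snr_db") |>
    tidyr::unnest_longer("snr_db") |>
    group_by(.data$scenario) |>
    mutate(subject_id = sprintf("S%02d", dplyr::row_number()), .before = 1) |>
    ungroup()
}
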