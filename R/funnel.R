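cta_stage_levels <- c("net_sample", "open", "excluded", "refused", "enrolled")

new_funnel <- function(identified, open, excluded, contacted, refused, enrolled,
                       deceased_subcount, in_progress_subcount) {
  out <- tibble::tibble(
    identified = as.integer(identified), open = as.integer(open),
    excluded = as.integer(excluded), contacted = as.integer(contacted),
    refused = as.integer(refused), enrolled = as.integer(enrolled),
    deceased_subcount = as.integer(deceased_subcount),
    in_progress_subcount = as.integer(in_progress_subcount)
  )
  class(out) <- c("cta_funnel", class(out))
  out
}

#' Recruitment funnel counts
#'
#' Classifies every study record of a replayed log by its final state into the
#' funnel stages `identified = open + excluded + contacted` and
#' `contacted = refused + enrolled`. Surveys in progress count as open (with a
#' separate sub-count); deceased records count inside the exclusion arm (with
#' a separate sub-count), so the conservation identities always hold.
#'
#' @param log An event-log tibble, or a registry as returned by [replay_log()].
#' @return A one-row `cta_funnel` tibble with columns `identified`, `open`,
#'   `excluded`, `contacted`, `refused`, `enrolled`, `deceased_subcount`,
#'   `in_progress_subcount`.
#' @examples
#' funnel_counts(cta_reference_log())
#' @export
funnel_counts <- function(log) {
  reg <- as_registry(log)
  st <- reg$state
  new_funnel(
    identified = length(st),
    open = sum(st %in% c("OPEN", "SURVEY_IN_PROGRESS")),
    excluded = sum(st %in% c("EXCLUDED", "DECEASED")),
    contacted = sum(st %in% c("REFUSED", "ENROLLED")),
    refused = sum(st == "REFUSED"),
    enrolled = sum(st == "ENROLLED"),
    deceased_subcount = sum(st == "DECEASED"),
    in_progress_subcount = sum(st == "SURVEY_IN_PROGRESS")
  )
}

#' Cases reviewed for eligibility
#'
#' A case counts as reviewed when the practice staff acted on the alert at
#' all, i.e. the record left the open arm: `excluded + contacted`.
#'
#' @param counts A `cta_funnel` row, as from [funnel_counts()].
#' @return An integer count.
#' @examples
#' reviewed_count(cta_reference_funnel()) # 5161
#' @export
reviewed_count <- function(counts) {
  as.integer(counts$excluded + counts$contacted)
}

#' Per-practice enrolment and target achievement
#'
#' One row per practice: net sample (identified records), enrolment, the
#' enrolment percentage, achievement of the fixed recruitment target, and a
#' small/large size class at the given net-sample threshold. Percentages are
#' rounded half-up to one decimal.
#'
#' @param log An event-log tibble or a [replay_log()] registry.
#' @param target Recruitment target per practice (default 200 enrolees).
#' @param threshold Net-sample size below which a practice is "small"
#'   (default 600).
#' @return A tibble with columns `practice_id`, `net_sample`, `enrolled`,
#'   `enrolment_pct`, `target_achievement_pct`, `size_class`.
#' @export
practice_table <- function(log, target = 200, threshold = 600) {
  stopifnot(target > 0)
  reg <- as_registry(log)
  reg |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(
      net_sample = dplyr::n(),
      enrolled = sum(.data$state == "ENROLLED"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      enrolment_pct = round_half_up(100 * .data$enrolled / .data$net_sample, 1),
      target_achievement_pct = round_half_up(100 * .data$enrolled / target, 1),
      size_class = ifelse(.data$net_sample < threshold, "small", "large")
    ) |>
    dplyr::arrange(.data$practice_id)
}

#' Pooled summary of small versus large practices
#'
#' Partitions practice rows at the net-sample `threshold` and pools each
#' stratum: practice count, total net sample, total enrolment, the pooled
#' enrolment percentage (rounded half-up to an integer), and the number of
#' poor recruiters (per-practice enrolment below `poor_cutoff` percent).
#'
#' @param rows A [practice_table()] tibble.
#' @param threshold Net-sample size separating small from large (default 600).
#' @param poor_cutoff Enrolment percentage below which a practice counts as a
#'   poor recruiter (default 5).
#' @return A tibble with one row per size class.
#' @export
size_strata_summary <- function(rows, threshold = 600, poor_cutoff = 5) {
  stopifnot(nrow(rows) > 0)
  rows |>
    dplyr::mutate(size_class = ifelse(.data$net_sample < threshold, "small", "large")) |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(
      n_practices = dplyr::n(),
      net_sample = sum(.data$net_sample),
      enrolled = sum(.data$enrolled),
      pooled_pct = round_half_up(100 * sum(.data$enrolled) / sum(.data$net_sample), 0),
      poor_recruiters = sum(.data$enrolment_pct < poor_cutoff),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$size_class))
}

#' CONSORT-style flow text
#'
#' A plain-text recruitment flow block for a funnel, with prose-style
#' percentages of the identified net sample (rounded half-up to integers).
#'
#' @param counts A `cta_funnel` row.
#' @return A single character string.
#' @export
consort_text <- function(counts) {
  pct <- function(x) round_half_up(100 * x / counts$identified, 0)
  paste0(
    "Identified (net sample): ", counts$identified, "\n",
    "  Open / no response:    ", counts$open, " (", pct(counts$open), "%)",
    " incl. ", counts$in_progress_subcount, " surveys in progress\n",
    "  Excluded:              ", counts$excluded, " (", pct(counts$excluded), "%)",
    " incl. ", counts$deceased_subcount, " deceased\n",
    "  Contacted:             ", counts$contacted, " (", pct(counts$contacted), "%)\n",
    "    Refused:             ", counts$refused, "\n",
    "    Enrolled:            ", counts$enrolled, "\n",
    "Reviewed for eligibility: ", reviewed_count(counts),
    " (", pct(reviewed_count(counts)), "%)\n"
  )
}

# round half away from zero, the convention of the reference tables
# (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# accept either a raw event log or an already-replayed registry
as_registry <- function(log) {
  if ("state" %in% names(log) && !"kind" %in% names(log)) {
    return(log)
  }
  replay_log(log)
}
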