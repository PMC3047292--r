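#' Demography by recruitment stage
#'
#' Tabulates study records by recruitment stage and demographic stratum. Every
#' record contributes to `net_sample` and to exactly one of the outcome stages
#' (`open` includes surveys in progress; `excluded` includes deceased
#' records). Percentages are within-stage shares over the five strata,
#' rounded half-up to one decimal.
#'
#' @param log An event-log tibble or a [replay_log()] registry.
#' @return A tibble with columns `stage`, `stratum`, `sex`, `n`, `pct`, of
#'   class `cta_strata`.
#' @examples
#' stage_demography(cta_reference_log())
#' @export
stage_demography <- function(log) {
  reg <- as_registry(log)
  stage <- dplyr::case_when(
    reg$state %in% c("OPEN", "SURVEY_IN_PROGRESS") ~ "open",
    reg$state %in% c("EXCLUDED", "DECEASED") ~ "excluded",
    reg$state == "REFUSED" ~ "refused",
    reg$state == "ENROLLED" ~ "enrolled"
  )
  long <- tibble::tibble(
    stage = c(rep("net_sample", nrow(reg)), stage),
    stratum = rep(reg$age_band, 2L)
  )
  out <- long |>
    dplyr::count(
      stage = factor(.data$stage, levels = cta_stage_levels),
      stratum = factor(.data$stratum, levels = cta_strata),
      .drop = FALSE
    ) |>
    dplyr::mutate(
      stratum = as.character(.data$stratum),
      sex = substr(.data$stratum, 1L, 1L)
    ) |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / pmax(sum(.data$n), 1L), 1)) |>
    dplyr::ungroup() |>
    dplyr::select("stage", "stratum", "sex", "n", "pct")
  class(out) <- c("cta_strata", class(out))
  out
}

#' Sex and within-sex age shares by stage
#'
#' Reshapes a stage-by-stratum table into the conventional three-panel
#' summary: the share of women and men within each stage, then age-band
#' shares within women and within men. Percentages half-up to one decimal.
#'
#' @param strata A `cta_strata` tibble (see [stage_demography()] or
#'   [cta_reference_strata()]).
#' @param digits Decimal places for the half-up rounding (default 1).
#' @return A tibble with columns `panel`, `label`, and one percentage column
#'   per stage.
#' @export
demography_table <- function(strata, digits = 1) {
  sex_panel <- strata |>
    dplyr::group_by(.data$stage, .data$sex) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(
      pct = round_half_up(100 * .data$n / pmax(sum(.data$n), 1L), digits)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      panel = "sex",
      label = ifelse(.data$sex == "F", "Women", "Men")
    )
  age_panels <- strata |>
    dplyr::group_by(.data$stage, .data$sex) |>
    dplyr::mutate(
      pct = round_half_up(100 * .data$n / pmax(sum(.data$n), 1L), digits)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      panel = ifelse(.data$sex == "F", "women", "men"),
      label = substring(.data$stratum, 2L)
    )
  dplyr::bind_rows(
    sex_panel[, c("panel", "label", "stage", "pct")],
    age_panels[, c("panel", "label", "stage", "pct")]
  ) |>
    tidyr::pivot_wider(names_from = "stage", values_from = "pct") |>
    dplyr::arrange(factor(.data$panel, levels = c("sex", "women", "men")))
}

#' Chi-square test of demographic selection bias
#'
#' Pearson chi-square test on the 2-by-k contingency table of enrolled versus
#' comparison counts across demographic strata. The default mode
#' `enrolled_vs_rest` compares enrolees against net-sample non-enrolees,
#' preserving the independence of the two groups; `enrolled_vs_net` keeps the
#' overlapping net-sample column for descriptive comparison.
#'
#' @param net_counts,enrolled_counts Named non-negative counts per stratum
#'   (same names/order). With `enrolled_vs_rest`, `enrolled <= net` must hold
#'   per stratum.
#' @param mode `"enrolled_vs_rest"` (default) or `"enrolled_vs_net"`.
#' @return A `cta_bias_test` object with elements `statistic`, `df`,
#'   `p_value`, `table_used`, `mode`. [tidy()] and [glance()] methods apply.
#' @examples
#' chi_square_bias_test(c(F = 11574, M = 4493), c(F = 1240, M = 286))
#' @export
chi_square_bias_test <- function(net_counts, enrolled_counts,
                                 mode = c("enrolled_vs_rest", "enrolled_vs_net")) {
  mode <- match.arg(mode)
  if (length(net_counts) != length(enrolled_counts)) {
    rlang::abort("count vectors differ in length", class = "cta_invalid_input")
  }
  if (any(net_counts < 0) || any(enrolled_counts < 0)) {
    rlang::abort("counts must be non-negative", class = "cta_invalid_input")
  }
  other <- if (mode == "enrolled_vs_rest") net_counts - enrolled_counts else net_counts
  if (mode == "enrolled_vs_rest" && any(other < 0)) {
    rlang::abort("enrolled exceeds net in some stratum", class = "cta_invalid_input")
  }
  tab <- rbind(enrolled = enrolled_counts, comparison = other)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    rlang::abort("degenerate table: a zero expected cell", class = "cta_degenerate_table")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = unname(ht$p.value),
      table_used = tab,
      mode = mode
    ),
    class = "cta_bias_test"
  )
}

#' @export
print.cta_bias_test <- function(x, ...) {
  cat(
    "Chi-square selection-bias test (", x$mode, ")\n",
    "X-squared = ", format(x$statistic), ", df = ", x$df,
    ", p = ", format.pval(x$p_value), "\n",
    sep = ""
  )
  invisible(x)
}

#' Representation ratio of a stratum
#'
#' A stratum's enrolled share divided by its net-sample share (both unrounded,
#' within the supplied table); 1 means proportional enrolment, below 1 means
#' under-representation. Scale-invariant in the counts.
#'
#' @param strata A `cta_strata`-shaped tibble with at least the stages
#'   `net_sample` and `enrolled` (any subset of strata, e.g. a within-sex
#'   panel).
#' @param stratum Optional stratum label; if omitted, ratios for all strata
#'   in the table are returned as a named vector.
#' @return A numeric ratio, or named vector of ratios.
#' @examples
#' representation_ratio(cta_reference_strata() |> dplyr::filter(sex == "M"))
#' @export
representation_ratio <- function(strata, stratum = NULL) {
  wide <- strata |>
    dplyr::filter(.data$stage %in% c("net_sample", "enrolled")) |>
    tidyr::pivot_wider(
      id_cols = "stratum", names_from = "stage", values_from = "n"
    )
  net_share <- wide$net_sample / sum(wide$net_sample)
  enr_share <- wide$enrolled / sum(wide$enrolled)
  ratios <- stats::setNames(enr_share / net_share, wide$stratum)
  if (is.null(stratum)) {
    return(ratios)
  }
  if (!stratum %in% wide$stratum || net_share[match(stratum, wide$stratum)] == 0) {
    rlang::abort(
      paste0("stratum ", stratum, " absent or has zero net share"),
      class = "cta_undefined_ratio"
    )
  }
  ratios[[stratum]]
}

#' Registry-consistency audit
#'
#' Capture completeness of the pseudonymised real-time registry against a
#' full panel query: the fraction of oracle-identified records that the
#' registry also holds. Software downtime lowers it.
#'
#' @param registry_ids,oracle_ids Character vectors (or sets) of study IDs;
#'   `oracle_ids` must be non-empty.
#' @return The overlap fraction in `[0, 1]`.
#' @export
registry_consistency <- function(registry_ids, oracle_ids) {
  oracle_ids <- unique(oracle_ids)
  if (length(oracle_ids) == 0L) {
    rlang::abort("`oracle_ids` is empty", class = "cta_invalid_input")
  }
  length(intersect(unique(registry_ids), oracle_ids)) / length(oracle_ids)
}

#' Adaptive reminder-suppression policy
#'
#' A policy that withholds the on-screen reminder for strata whose enrolled
#' share exceeds their net-sample share by more than `tolerance` percentage
#' points, until the selection levels reflect the net sample again. No
#' suppression activates before `min_enrolled` enrolments.
#'
#' @param tolerance Maximum allowed excess, in percentage points (default 5).
#' @param min_enrolled Minimum enrolments before suppression activates
#'   (default 50).
#' @param suppressed_strata Currently suppressed strata (default none).
#' @return A `cta_suppression_policy` object.
#' @export
suppression_policy <- function(tolerance = 5, min_enrolled = 50,
                               suppressed_strata = character()) {
  stopifnot(tolerance >= 0, min_enrolled >= 0)
  if (!all(suppressed_strata %in% cta_strata)) {
    rlang::abort("unknown stratum in `suppressed_strata`", class = "cta_invalid_input")
  }
  structure(
    list(
      tolerance = tolerance, min_enrolled = min_enrolled,
      suppressed_strata = suppressed_strata
    ),
    class = "cta_suppression_policy"
  )
}

#' Update a suppression policy from current selection levels
#'
#' Recomputes the suppressed set from a stage-by-stratum table: a stratum is
#' suppressed iff its enrolled share exceeds its net-sample share (unrounded,
#' in percentage points) by more than the policy tolerance; a previously
#' suppressed stratum is released as soon as its excess falls to or below the
#' tolerance. Below `min_enrolled` total enrolments nothing is suppressed.
#'
#' @param policy A [suppression_policy()].
#' @param strata A `cta_strata`-shaped tibble with stages `net_sample` and
#'   `enrolled`.
#' @return The updated policy.
#' @export
update_suppression <- function(policy, strata) {
  wide <- strata |>
    dplyr::filter(.data$stage %in% c("net_sample", "enrolled")) |>
    tidyr::pivot_wider(
      id_cols = "stratum", names_from = "stage", values_from = "n"
    )
  total_enrolled <- sum(wide$enrolled)
  if (total_enrolled < policy$min_enrolled) {
    policy$suppressed_strata <- character()
    return(policy)
  }
  excess <- 100 * (wide$enrolled / total_enrolled - wide$net_sample / sum(wide$net_sample))
  policy$suppressed_strata <- wide$stratum[excess > policy$tolerance]
  policy
}

#' Total-variation distance between two demographic compositions
#'
#' Half the L1 distance between the normalised share vectors of two count (or
#' share) vectors over the same strata; 0 means identical composition.
#'
#' @param p,q Non-negative numeric vectors of equal length with positive sums.
#' @return A number in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q), sum(p) > 0, sum(q) > 0)
  sum(abs(p / sum(p) - q / sum(q))) / 2
}
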