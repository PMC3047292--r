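#' Reference study: enrolment and target achievement by practice
#'
#' Per-practice net sample and enrolment from the reference study — a
#' 12-month osteoporosis-risk survey recruited through a clinical trial alert
#' tool in 25 German general practices. The per-practice recruitment target
#' was 200 enrolled patients.
#'
#' @return A tibble with columns `practice_id`, `net_sample`, `enrolled`.
#' @export
cta_reference_practices <- function() {
  tibble::tibble(
    practice_id = sprintf("P%02d", 1:25),
    net_sample = c(
      162L, 255L, 256L, 334L, 350L, 386L, 390L, 407L, 454L, 455L, 505L, 511L,
      596L, 616L, 636L, 689L, 801L, 808L, 901L, 905L, 986L, 1021L, 1150L,
      1177L, 1316L
    ),
    enrolled = c(
      14L, 31L, 30L, 87L, 82L, 71L, 41L, 53L, 115L, 93L, 4L, 78L, 54L, 99L,
      26L, 11L, 133L, 31L, 41L, 9L, 202L, 54L, 85L, 55L, 27L
    )
  )
}

#' Reference study: recruitment funnel totals
#'
#' Stage totals of the reference study's recruitment funnel. Ignored
#' reminders and unfinished surveys count as open; the 22 EPRs of deceased
#' patients sit inside the exclusion arm as a sub-count, so
#' `identified = open + excluded + contacted` and
#' `contacted = refused + enrolled` hold exactly.
#'
#' @return A one-row [funnel_counts()]-shaped tibble.
#' @export
cta_reference_funnel <- function() {
  new_funnel(
    identified = 16067L, open = 10906L, excluded = 3248L, contacted = 1913L,
    refused = 387L, enrolled = 1526L, deceased_subcount = 22L,
    in_progress_subcount = 43L
  )
}

#' Reference study: demography by recruitment stage
#'
#' Stage-by-stratum counts of the reference study (the five sex/age strata of
#' [cta_strata] across the stages net sample, open, excluded, refused,
#' enrolled). Stage and sex totals are as published; the interior age-band
#' counts are reconstructed from the published within-sex percentages by
#' constrained rounding under the funnel-conservation constraint (each
#' stratum's net count equals the sum of its outcome counts). The published
#' within-men shares of the open stage (41.5/58.5 for 70-79/80+) are
#' irreconcilable with the published men's net-sample shares (56.4/43.6)
#' under conservation; interchanging the two cells restores consistency to
#' within rounding, so the reconstruction adopts the interchanged values —
#' the one place this table deviates from the source print.
#'
#' @return A tibble with columns `stage`, `stratum`, `sex`, `n`.
#' @export
cta_reference_strata <- function() {
  counts <- matrix(
    c(
      # net_sample, open, excluded, refused, enrolled
      3377L, 2434L,  390L,  87L,  466L, # F60-69
      3748L, 2519L,  611L,  99L,  519L, # F70-79
      4449L, 2737L, 1376L,  81L,  255L, # F80+
      2536L, 1881L,  385L,  68L,  202L, # M70-79
      1957L, 1335L,  486L,  52L,   84L  # M80+
    ),
    nrow = 5L, byrow = TRUE,
    dimnames = list(cta_strata, c("net_sample", "open", "excluded", "refused", "enrolled"))
  )
  tibble::tibble(
    stage = factor(rep(colnames(counts), each = 5L), levels = colnames(counts)),
    stratum = rep(cta_strata, times = 5L),
    sex = substr(stratum, 1L, 1L),
    n = as.integer(counts) # column-major: stratum fastest within stage
  )
}

#' Reconstruct an event log consistent with the reference study
#'
#' Builds a synthetic pseudonymised event log whose replay reproduces the
#' reference study's published marginals: the funnel totals
#' ([cta_reference_funnel()]), the per-practice net sample and enrolment
#' ([cta_reference_practices()]), and the stage-by-stratum demography
#' ([cta_reference_strata()]). The joint allocation of strata to practices
#' and the event timestamps are deterministic conventions, not data: only
#' the marginals are faithful.
#'
#' @return An event-log tibble (see [replay_log()]) with 16,067 study records.
#' @export
cta_reference_log <- function() {
  prac <- cta_reference_practices()
  strata <- cta_reference_strata()
  fun <- cta_reference_funnel()

  # per-practice stage allocation: enrolled is published; refused and excluded
  # are spread proportionally to net sample (largest remainder); open absorbs
  # the remainder so the funnel conserves within every practice
  refused_p <- alloc_largest_remainder(fun$refused, prac$net_sample)
  excluded_p <- alloc_largest_remainder(fun$excluded, prac$net_sample)
  open_p <- prac$net_sample - prac$enrolled - refused_p - excluded_p
  stopifnot(all(open_p >= 0L))

  stage_by_practice <- list(
    open = open_p, excluded = excluded_p, refused = refused_p,
    enrolled = prac$enrolled
  )
  wide <- tidyr::pivot_wider(strata, names_from = "stage", values_from = "n")

  records <- purrr::map_dfr(names(stage_by_practice), function(st) {
    per_prac <- stage_by_practice[[st]]
    per_stratum <- stats::setNames(wide[[st]], wide$stratum)
    cells <- northwest_fill(per_prac, per_stratum)
    tibble::tibble(
      practice_id = rep(prac$practice_id[cells$row], cells$n),
      stratum = rep(names(per_stratum)[cells$col], cells$n),
      class = st
    )
  })

  # sub-counts: 43 unfinished surveys (counted open) and 22 deceased EPRs
  # (counted inside the exclusion arm)
  i_open <- which(records$class == "open")
  records$class[i_open[seq_len(fun$in_progress_subcount)]] <- "in_progress"
  i_excl <- which(records$class == "excluded")
  records$class[i_excl[seq_len(fun$deceased_subcount)]] <- "deceased"

  records <- records[order(records$practice_id), ]
  records$study_id <- sprintf("R%05d", seq_len(nrow(records)))
  records$sex <- substr(records$stratum, 1L, 1L)

  # one deterministic visit day per record, spread across the 12-month window
  start <- as.POSIXct("2007-05-01 09:00:00", tz = "UTC")
  day_in_practice <- stats::ave(
    seq_len(nrow(records)), records$practice_id,
    FUN = function(i) floor((seq_along(i) - 1L) * 364 / max(length(i) - 1L, 1L))
  )
  records$visit <- start + day_in_practice * 86400

  seqs <- list(
    open = c("epr_open", "click_off"),
    in_progress = c("epr_open", "contact", "consent", "survey_start"),
    excluded = c("epr_open", "exclude"),
    deceased = c("epr_open", "deceased_noted"),
    refused = c("epr_open", "contact", "refuse"),
    enrolled = c("epr_open", "contact", "consent", "survey_start", "survey_complete")
  )
  kinds <- seqs[records$class]
  n_ev <- lengths(kinds)
  reasons <- rep(cta_exclusion_reasons, length.out = sum(records$class == "excluded"))

  log <- tibble::tibble(
    timestamp = rep(records$visit, n_ev) + (unlist(lapply(n_ev, seq_len)) - 1L) * 60,
    practice_id = rep(records$practice_id, n_ev),
    study_id = rep(records$study_id, n_ev),
    kind = unlist(kinds, use.names = FALSE),
    sex = rep(records$sex, n_ev),
    age_band = rep(records$stratum, n_ev),
    payload = NA_character_,
    recorded = TRUE
  )
  log$payload[log$kind == "exclude"] <- reasons
  dplyr::arrange(log, .data$practice_id, .data$timestamp, .data$study_id)
}

# integer allocation of `total` proportional to `weights` (largest remainder)
alloc_largest_remainder <- function(total, weights) {
  q <- total * weights / sum(weights)
  base <- floor(q)
  short <- total - sum(base)
  extra <- order(q - base, decreasing = TRUE)[seq_len(short)]
  out <- as.integer(base)
  out[extra] <- out[extra] + 1L
  out
}

# fill a contingency table with given margins by the northwest-corner rule;
# returns occupied cells as (row, col, n)
northwest_fill <- function(row_totals, col_totals) {
  stopifnot(sum(row_totals) == sum(col_totals))
  rows <- integer(0); cols <- integer(0); ns <- integer(0)
  i <- 1L; j <- 1L
  r <- row_totals; s <- col_totals
  while (i <= length(r) && j <= length(s)) {
    take <- min(r[i], s[j])
    if (take > 0L) {
      rows <- c(rows, i); cols <- c(cols, j); ns <- c(ns, take)
    }
    r[i] <- r[i] - take
    s[j] <- s[j] - take
    if (r[i] == 0L) i <- i + 1L
    if (j <= length(s) && s[j] == 0L) j <- j + 1L
  }
  list(row = rows, col = cols, n = ns)
}
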