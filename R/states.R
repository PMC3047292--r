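#' @name recruitment-states
#' @title The recruitment state machine
#'
#' @description
#' Every identified patient starts `OPEN`. Ignored reminders and unfinished
#' surveys remain "open"; exclusion, refusal, enrolment and a noted death are
#' absorbing. Only `OPEN` and `SURVEY_IN_PROGRESS` records admit further
#' recruitment events; on absorbing states only a plain EPR opening (which no
#' longer fires the alert) is tolerated.
#'
#' Event kinds: `epr_open`, `click_off`, `exclude` (carries a reason),
#' `contact`, `refuse`, `consent`, `survey_start`, `survey_interrupt`,
#' `survey_complete`, `deceased_noted`.
NULL

#' @rdname recruitment-states
#' @format `cta_states`, `cta_event_kinds` and `cta_exclusion_reasons` are
#'   character vectors of the legal state, event-kind and exclusion-reason
#'   labels.
#' @export
cta_states <- c("OPEN", "SURVEY_IN_PROGRESS", "EXCLUDED", "REFUSED", "ENROLLED", "DECEASED")

#' @rdname recruitment-states
#' @export
cta_event_kinds <- c(
  "epr_open", "click_off", "exclude", "contact", "refuse", "consent",
  "survey_start", "survey_interrupt", "survey_complete", "deceased_noted"
)

#' @rdname recruitment-states
#' @export
cta_exclusion_reasons <- c(
  "psychiatric_disorder", "language_barrier", "not_physically_present", "other"
)

cta_absorbing <- c("EXCLUDED", "REFUSED", "ENROLLED", "DECEASED")

#' Apply one recruitment event to a state
#'
#' The pure transition function of the recruitment state machine. Illegal
#' events raise a condition: events on an absorbing state (other than a plain
#' `epr_open`) signal `cta_terminal_state`; out-of-order events (e.g.
#' `survey_complete` without a running survey) signal `cta_protocol_error`.
#'
#' @param state A single state label (see [cta_states]).
#' @param kind A single event kind (see [cta_event_kinds]).
#' @return The new state label.
#' @examples
#' apply_event("OPEN", "click_off")       # stays OPEN, reminder re-fires
#' apply_event("OPEN", "exclude")         # EXCLUDED, recruitment finalised
#' @export
apply_event <- function(state, kind) {
  if (!state %in% cta_states) {
    rlang::abort(paste0("unknown state: ", state), class = "cta_protocol_error")
  }
  if (!kind %in% cta_event_kinds) {
    rlang::abort(paste0("unknown event kind: ", kind), class = "cta_protocol_error")
  }
  if (state %in% cta_absorbing) {
    if (kind == "epr_open") return(state)
    rlang::abort(
      paste0("recruitment event `", kind, "` on terminal state ", state),
      class = "cta_terminal_state"
    )
  }
  if (state == "OPEN") {
    new <- switch(kind,
      epr_open = "OPEN", click_off = "OPEN", contact = "OPEN", consent = "OPEN",
      exclude = "EXCLUDED", refuse = "REFUSED", survey_start = "SURVEY_IN_PROGRESS",
      deceased_noted = "DECEASED",
      NULL
    )
  } else { # SURVEY_IN_PROGRESS
    new <- switch(kind,
      epr_open = "SURVEY_IN_PROGRESS", survey_interrupt = "SURVEY_IN_PROGRESS",
      survey_complete = "ENROLLED",
      NULL
    )
  }
  if (is.null(new)) {
    rlang::abort(
      paste0("event `", kind, "` is out of order in state ", state),
      class = "cta_protocol_error"
    )
  }
  new
}

#' Replay an event log into a pseudonymised registry
#'
#' Folds every record's time-ordered events through [apply_event()], checking
#' the protocol along the way: the first event of a record must be an
#' `epr_open`; any other kind must follow an `epr_open` for the same record
#' on the same calendar day; `refuse` and `consent` require a prior `contact`;
#' `exclude` must carry a reason from [cta_exclusion_reasons]. Replay is
#' deterministic: the same log always yields the same registry.
#'
#' @param log An event-log tibble with columns `timestamp` (`POSIXct`),
#'   `practice_id`, `study_id`, `kind`, `sex`, `age_band` and optionally
#'   `payload` (exclusion reason) and `recorded`. Rows with `recorded = FALSE`
#'   (software downtime) are invisible to the registry and are skipped.
#' @return A tibble with one row per study record: `study_id`, `practice_id`,
#'   `sex`, `age_band`, `state`, `exclusion_reason`, `n_events`.
#' @export
replay_log <- function(log) {
  log <- check_log(log)
  log <- dplyr::filter(log, .data$recorded)
  if (nrow(log) == 0L) {
    return(tibble::tibble(
      study_id = character(), practice_id = character(), sex = character(),
      age_band = character(), state = character(), exclusion_reason = character(),
      n_events = integer()
    ))
  }
  ord <- order(log$study_id, log$timestamp)
  id <- log$study_id[ord]
  kind <- log$kind[ord]
  ts <- log$timestamp[ord]
  day <- as.Date(ts, tz = "UTC")
  payload <- if ("payload" %in% names(log)) log$payload[ord] else rep(NA_character_, length(id))

  new_rec <- c(TRUE, id[-1L] != id[-length(id)])
  state <- character(0)
  cur <- ""
  st <- ""
  contacted <- FALSE
  open_day <- as.Date(NA)
  res_id <- unique(id)
  res_state <- character(length(res_id))
  k <- 0L
  for (i in seq_along(id)) {
    if (new_rec[i]) {
      if (k > 0L) res_state[k] <- st
      k <- k + 1L
      st <- "OPEN"
      contacted <- FALSE
      open_day <- as.Date(NA)
      if (kind[i] != "epr_open") {
        rlang::abort(
          paste0("record ", id[i], " starts with `", kind[i], "`, not `epr_open`"),
          class = "cta_protocol_error"
        )
      }
    }
    if (kind[i] == "epr_open") {
      open_day <- day[i]
    } else {
      if (is.na(open_day) || day[i] != open_day) {
        rlang::abort(
          paste0("event `", kind[i], "` for ", id[i], " does not follow a same-day epr_open"),
          class = "cta_protocol_error"
        )
      }
      if (kind[i] %in% c("refuse", "consent") && !contacted) {
        rlang::abort(
          paste0("`", kind[i], "` without prior contact for ", id[i]),
          class = "cta_protocol_error"
        )
      }
      if (kind[i] == "exclude" &&
          (is.na(payload[i]) || !payload[i] %in% cta_exclusion_reasons)) {
        rlang::abort(
          paste0("exclude event for ", id[i], " lacks a valid reason"),
          class = "cta_protocol_error"
        )
      }
      if (kind[i] == "contact") contacted <- TRUE
    }
    st <- apply_event(st, kind[i])
  }
  res_state[k] <- st

  first <- log[ord, ][new_rec, c("study_id", "practice_id", "sex", "age_band")]
  reasons <- stats::setNames(rep(NA_character_, length(res_id)), res_id)
  excl <- !is.na(payload) & kind == "exclude"
  reasons[id[excl]] <- payload[excl]
  tibble::tibble(
    study_id = res_id,
    practice_id = first$practice_id,
    sex = first$sex,
    age_band = first$age_band,
    state = res_state,
    exclusion_reason = unname(reasons),
    n_events = as.integer(table(factor(id, levels = res_id)))
  )
}

#' Should the on-screen reminder fire?
#'
#' The alert fires for records that are still recruitable (`OPEN` or
#' `SURVEY_IN_PROGRESS`), unless an active [suppression_policy()] currently
#' suppresses the record's stratum.
#'
#' @param state Character vector of recruitment states.
#' @param stratum Character vector of stratum labels (see [cta_strata]);
#'   only consulted when `policy` is given.
#' @param policy A [suppression_policy()], or `NULL` for unconditional alerts.
#' @return Logical vector.
#' @export
should_alert <- function(state, stratum = NULL, policy = NULL) {
  active <- state %in% c("OPEN", "SURVEY_IN_PROGRESS")
  if (is.null(policy) || length(policy$suppressed_strata) == 0L) {
    return(active)
  }
  if (is.null(stratum)) {
    rlang::abort("`stratum` is required when a suppression policy is given",
                 class = "cta_invalid_input")
  }
  active & !stratum %in% policy$suppressed_strata
}

check_log <- function(log) {
  needed <- c("timestamp", "practice_id", "study_id", "kind", "sex", "age_band")
  missing <- setdiff(needed, names(log))
  if (length(missing) > 0L) {
    rlang::abort(
      paste0("event log lacks column(s): ", paste(missing, collapse = ", ")),
      class = "cta_invalid_input"
    )
  }
  if (!"recorded" %in% names(log)) log$recorded <- TRUE
  log$recorded[is.na(log$recorded)] <- TRUE
  bad <- !log$kind %in% cta_event_kinds
  if (any(bad)) {
    rlang::abort(
      paste0("unknown event kind(s): ", paste(unique(log$kind[bad]), collapse = ", ")),
      class = "cta_invalid_input"
    )
  }
  log
}
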