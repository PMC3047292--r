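log_schema_keys <- c(
  "timestamp", "practice_id", "study_id", "kind", "sex", "age_band",
  "payload", "recorded"
)

#' Write an event log as JSON Lines
#'
#' One JSON object per line with keys `timestamp` (ISO-8601, UTC),
#' `practice_id`, `study_id`, `kind`, `sex`, `age_band`, `payload` (present
#' only on exclusions) and `recorded`. The serialisation is byte-deterministic
#' for a given log.
#'
#' @param log An event-log tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  log <- check_log(log)
  esc <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
  payload <- if ("payload" %in% names(log)) log$payload else rep(NA_character_, nrow(log))
  lines <- paste0(
    '{"timestamp":"', format(log$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    '","practice_id":"', esc(log$practice_id),
    '","study_id":"', esc(log$study_id),
    '","kind":"', log$kind,
    '","sex":"', log$sex,
    '","age_band":"', log$age_band, '"',
    ifelse(is.na(payload), "", paste0(',"payload":"', payload, '"')),
    ',"recorded":', ifelse(log$recorded, "true", "false"), "}"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-Lines event log
#'
#' Parses and validates an event-log file: every line must be a standalone
#' JSON object with exactly the schema keys (malformed or off-schema lines
#' raise a parse error naming the line number), and timestamps must be
#' non-decreasing within each practice (violations raise a protocol error).
#'
#' @param path Path to a file written by [write_event_log()].
#' @return An event-log tibble in file order.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "cta_invalid_input")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  required <- setdiff(log_schema_keys, c("payload", "recorded"))
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        rlang::abort(
          paste0("parse error at line ", i, ": ", conditionMessage(e)),
          class = "cta_parse_error"
        )
      }
    )
    extra <- setdiff(names(obj), log_schema_keys)
    missing <- setdiff(required, names(obj))
    if (length(extra) > 0 || length(missing) > 0) {
      rlang::abort(
        paste0(
          "parse error at line ", i, ": ",
          if (length(missing) > 0) paste0("missing key(s) ", paste(missing, collapse = ", ")),
          if (length(extra) > 0) paste0("off-schema key(s) ", paste(extra, collapse = ", "))
        ),
        class = "cta_parse_error"
      )
    }
    if (!obj$kind %in% cta_event_kinds) {
      rlang::abort(paste0("parse error at line ", i, ": unknown kind ", obj$kind),
                   class = "cta_parse_error")
    }
    parsed[[i]] <- obj
  }
  get_chr <- function(k, default = NA_character_) {
    vapply(parsed, function(o) if (is.null(o[[k]])) default else as.character(o[[k]]),
           character(1))
  }
  ts <- as.POSIXct(get_chr("timestamp"), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad_ts <- which(is.na(ts))
  if (length(bad_ts) > 0) {
    rlang::abort(paste0("parse error at line ", bad_ts[1], ": bad timestamp"),
                 class = "cta_parse_error")
  }
  log <- tibble::tibble(
    timestamp = ts,
    practice_id = get_chr("practice_id"),
    study_id = get_chr("study_id"),
    kind = get_chr("kind"),
    sex = get_chr("sex"),
    age_band = get_chr("age_band"),
    payload = get_chr("payload"),
    recorded = vapply(parsed, function(o) isTRUE(o$recorded) || is.null(o$recorded), logical(1))
  )
  viol <- log |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp), .groups = "drop")
  if (any(!viol$ok)) {
    rlang::abort(
      paste0("timestamps not non-decreasing within practice ",
             paste(viol$practice_id[!viol$ok], collapse = ", ")),
      class = "cta_protocol_error"
    )
  }
  log
}

#' Read a declarative run configuration
#'
#' Loads a YAML file describing a whole simulation run: the study window,
#' the recruitment target and size threshold, staff behaviour, an optional
#' suppression policy, the master seed, and one block per practice.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `practices` (list of [practice_config()]),
#'   `behaviour`, `policy` (or `NULL`), `seed`, `target`, `size_threshold`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  study <- y$study %||% list()
  start <- as.Date(study$start %||% "2007-05-01")
  months <- study$months %||% 12
  beh <- do.call(staff_behaviour, as_args(y$staff, names(formals(staff_behaviour))))
  pol <- NULL
  if (isTRUE(y$suppression$enabled)) {
    pol <- suppression_policy(
      tolerance = y$suppression$tolerance %||% 5,
      min_enrolled = y$suppression$min_enrolled %||% 50
    )
  }
  practices <- purrr::map(y$practices, function(p) {
    dem <- if (is.null(p$demography)) cta_net_demography() else unlist(p$demography)
    practice_config(
      practice_id = p$practice_id,
      panel_size = p$panel_size,
      demography = dem,
      visit_rate = p$visit_rate %||% 0.5,
      not_present_prob = p$not_present_prob %||% 0.2,
      downtime_windows = p$downtime %||% list(),
      study_start = start,
      study_months = months,
      deceased_frac = p$deceased_frac %||% 0.0015
    )
  })
  ids <- vapply(practices, function(p) p$practice_id, character(1))
  if (anyDuplicated(ids)) {
    rlang::abort("practice_id values must be unique", class = "cta_config_error")
  }
  list(
    practices = practices, behaviour = beh, policy = pol,
    seed = y$seed %||% 1, target = y$target %||% 200,
    size_threshold = y$size_threshold %||% 600
  )
}

as_args <- function(x, allowed) {
  if (is.null(x)) return(list())
  x[intersect(names(x), allowed)]
}

#' Write the per-practice enrolment table as CSV
#'
#' @param rows A [practice_table()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_practice_csv <- function(rows, path) {
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the stage-by-stratum demography table as CSV
#'
#' Emits the three-panel [demography_table()] (stage columns, stratum rows).
#'
#' @param strata A `cta_strata` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demography_csv <- function(strata, path) {
  utils::write.csv(as.data.frame(demography_table(strata)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
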