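#' Net-sample demography of the reference study
#'
#' The default stratum composition for simulated panels: 72% women split
#' 29.2/32.4/38.4 across 60-69/70-79/80+, 28% men split 56.4/43.6 across
#' 70-79/80+.
#'
#' @return A named probability vector over [cta_strata].
#' @export
cta_net_demography <- function() {
  c(
    "F60-69" = 0.72 * 0.292, "F70-79" = 0.72 * 0.324, "F80+" = 0.72 * 0.384,
    "M70-79" = 0.28 * 0.564, "M80+" = 0.28 * 0.436
  )
}

#' Configuration of one simulated practice
#'
#' Describes a general practice for the simulator: how many net-sample
#' eligible patients it has, their stratum composition, how often their EPRs
#' are opened, how often an EPR is opened without the patient physically
#' present, and software downtime windows during which the tool records
#' nothing.
#'
#' @param practice_id Site label.
#' @param panel_size Number of net-sample eligible patients.
#' @param demography Named probability vector over [cta_strata]; must sum to
#'   1 within 1e-9.
#' @param visit_rate Expected EPR-open events per patient per study month.
#' @param not_present_prob Probability an EPR-open occurs without the patient
#'   physically present.
#' @param downtime_windows List of `c(start, end)` date pairs (or
#'   `list(start=, end=)`) within the study period.
#' @param study_start First day of the study window.
#' @param study_months Study duration in months (default 12).
#' @param deceased_frac Fraction of panel patients who are deceased but whose
#'   EPRs may still be opened (default 0.0015).
#' @param practice_secret Key material for [pseudonymize()]; defaults to a
#'   label-derived placeholder.
#' @return A `cta_practice_config` object.
#' @export
practice_config <- function(practice_id, panel_size,
                            demography = cta_net_demography(),
                            visit_rate = 0.5, not_present_prob = 0.2,
                            downtime_windows = list(),
                            study_start = as.Date("2007-05-01"),
                            study_months = 12, deceased_frac = 0.0015,
                            practice_secret = paste0("secret-", practice_id)) {
  if (!setequal(names(demography), cta_strata)) {
    rlang::abort("`demography` must be named over the five study strata",
                 class = "cta_config_error")
  }
  demography <- demography[cta_strata]
  if (abs(sum(demography) - 1) > 1e-9 || any(demography < 0)) {
    rlang::abort("`demography` must be a probability vector summing to 1",
                 class = "cta_config_error")
  }
  if (panel_size < 0 || visit_rate < 0 || study_months <= 0 ||
      not_present_prob < 0 || not_present_prob > 1 ||
      deceased_frac < 0 || deceased_frac > 1) {
    rlang::abort("rates and sizes out of range", class = "cta_config_error")
  }
  study_start <- as.Date(study_start)
  study_end <- seq(study_start, by = paste(study_months, "months"), length.out = 2)[2]
  windows <- purrr::map_dfr(downtime_windows, function(w) {
    w <- unlist(w, use.names = FALSE)
    tibble::tibble(start = as.Date(w[1]), end = as.Date(w[2]))
  })
  if (nrow(windows) > 0 &&
      (any(windows$start > windows$end) || any(windows$start < study_start) ||
       any(windows$end > study_end))) {
    rlang::abort("downtime windows must lie within the study period",
                 class = "cta_config_error")
  }
  structure(
    list(
      practice_id = practice_id, panel_size = as.integer(panel_size),
      demography = demography, visit_rate = visit_rate,
      not_present_prob = not_present_prob, downtime_windows = windows,
      study_start = study_start, study_end = study_end,
      study_months = study_months, deceased_frac = deceased_frac,
      practice_secret = practice_secret
    ),
    class = "cta_practice_config"
  )
}

#' Staff recruitment behaviour
#'
#' Per-visit decision probabilities of the practice staff. At every recorded
#' EPR-open with an active alert the staff acts with probability `p_respond`
#' (times an optional stratum multiplier, capped at 1), otherwise clicks the
#' reminder off. A response branches to exclusion or patient contact; a
#' contact branches to refusal or consent and survey; a started survey is
#' interrupted (to be resumed at the patient's next visit) with
#' `p_interrupt_given_start`, otherwise completed.
#'
#' The defaults are calibrated so that, at the default visit rate of 0.5
#' EPR-opens per patient-month over 12 months, the expected share of reviewed
#' cases is 32%, of which 63% are excluded, and 20% of contacts refuse —
#' the stage proportions of the reference study.
#'
#' @param p_respond Per-visit probability that an active alert is acted on.
#' @param p_exclude_given_respond Probability a response is an exclusion.
#' @param p_refuse_given_contact Probability a contacted patient refuses.
#' @param p_interrupt_given_start Probability a started survey is interrupted.
#' @param contact_multipliers Optional named per-stratum multiplicative
#'   weights on `p_respond` (a selection-bias injector); must be >= 0.
#' @return A `cta_staff_behaviour` object.
#' @export
staff_behaviour <- function(p_respond = 0.064,
                            p_exclude_given_respond = 3248 / 5161,
                            p_refuse_given_contact = 387 / 1913,
                            p_interrupt_given_start = 43 / 1569,
                            contact_multipliers = NULL) {
  probs <- c(p_respond, p_exclude_given_respond, p_refuse_given_contact,
             p_interrupt_given_start)
  if (any(probs < 0) || any(probs > 1)) {
    rlang::abort("probabilities must lie in [0, 1]", class = "cta_config_error")
  }
  if (!is.null(contact_multipliers)) {
    if (any(contact_multipliers < 0) ||
        !all(names(contact_multipliers) %in% cta_strata)) {
      rlang::abort("`contact_multipliers` must be >= 0 and named over strata",
                   class = "cta_config_error")
    }
  }
  structure(
    list(
      p_respond = p_respond,
      p_exclude_given_respond = p_exclude_given_respond,
      p_refuse_given_contact = p_refuse_given_contact,
      p_interrupt_given_start = p_interrupt_given_start,
      contact_multipliers = contact_multipliers
    ),
    class = "cta_staff_behaviour"
  )
}

#' Generate a practice panel
#'
#' Draws `panel_size` patients i.i.d. from the configured stratum demography,
#' with birth dates uniform within each age band (women 60-69, 70-79, 80-94;
#' men 70-79, 80-94, evaluated at study start). Reproducible given `seed`.
#'
#' @param config A [practice_config()].
#' @param seed Integer seed.
#' @return A tibble of patient records: `internal_id`, `practice_id`, `sex`,
#'   `birth_date`, `stratum`, `deceased`.
#' @export
generate_panel <- function(config, seed) {
  n <- config$panel_size
  set.seed(seed)
  stratum <- if (n > 0) {
    sample(cta_strata, n, replace = TRUE, prob = config$demography)
  } else {
    character()
  }
  band_lo <- c("F60-69" = 60, "F70-79" = 70, "F80+" = 80, "M70-79" = 70, "M80+" = 80)
  band_hi <- c("F60-69" = 70, "F70-79" = 80, "F80+" = 95, "M70-79" = 80, "M80+" = 95)
  # +2/-2 day margin keeps uniform draws strictly inside the band despite
  # leap-day granularity
  age_days <- stats::runif(n, band_lo[stratum] * 365.25 + 2, band_hi[stratum] * 365.25 - 2)
  tibble::tibble(
    internal_id = sprintf("%s-%06d", config$practice_id, seq_len(n)),
    practice_id = rep(config$practice_id, n),
    sex = substr(stratum, 1L, 1L),
    birth_date = config$study_start - floor(age_days),
    stratum = stratum,
    deceased = stats::runif(n) < config$deceased_frac
  )
}

#' Simulate the stream of EPR-open events
#'
#' Each patient generates a Poisson number of EPR-opens (mean
#' `visit_rate * study_months`) on days uniform over the study window, at
#' times uniform within practice hours (08:00-18:00, so that follow-up events
#' minutes later stay on the same calendar day). Each
#' event is flagged `physically_present` with probability
#' `1 - not_present_prob`; events inside a downtime window are flagged
#' `recorded = FALSE` (invisible to the registry, visible to the oracle).
#'
#' @param panel A [generate_panel()] tibble.
#' @param config The matching [practice_config()].
#' @param seed Integer seed.
#' @return A time-ordered tibble of visits: patient columns plus `timestamp`,
#'   `physically_present`, `recorded`.
#' @export
simulate_visits <- function(panel, config, seed) {
  set.seed(seed)
  n_visits <- stats::rpois(nrow(panel), config$visit_rate * config$study_months)
  total <- sum(n_visits)
  n_days <- as.integer(config$study_end - config$study_start)
  day_idx <- floor(stats::runif(total, 0, n_days))
  tod <- floor(stats::runif(total, 8 * 3600, 18 * 3600 - 600)) # whole seconds
  ts <- as.POSIXct(config$study_start, tz = "UTC") + day_idx * 86400 + tod
  idx <- rep(seq_len(nrow(panel)), n_visits)
  visits <- tibble::tibble(
    timestamp = ts,
    internal_id = panel$internal_id[idx],
    practice_id = panel$practice_id[idx],
    sex = panel$sex[idx],
    birth_date = panel$birth_date[idx],
    deceased = panel$deceased[idx],
    physically_present = stats::runif(total) >= config$not_present_prob
  )
  visits$stratum <- age_band(visits$sex, visits$birth_date, as.Date(visits$timestamp, tz = "UTC"))
  day <- as.Date(visits$timestamp, tz = "UTC")
  down <- rep(FALSE, total)
  if (nrow(config$downtime_windows) > 0) {
    for (w in seq_len(nrow(config$downtime_windows))) {
      down <- down | (day >= config$downtime_windows$start[w] &
                        day <= config$downtime_windows$end[w])
    }
  }
  visits$recorded <- !down
  dplyr::arrange(visits, .data$timestamp)
}

#' Simulate staff recruitment decisions over a visit stream
#'
#' Walks the visit stream in time order and applies the [staff_behaviour()]
#' decision model at every recorded EPR-open whose record still alerts
#' (see [should_alert()]). Produces a complete recruitment event log whose
#' replay through [apply_event()] is always legal. With a
#' [suppression_policy()], the suppressed set is kept up to date from the
#' running registry counts, and suppressed strata receive no alert.
#'
#' @param visits A visit stream from [simulate_visits()] (possibly several
#'   practices bound together).
#' @param behaviour A [staff_behaviour()].
#' @param seed Integer seed.
#' @param policy Optional [suppression_policy()] for adaptive suppression.
#' @param secrets Named character vector of per-practice pseudonymisation
#'   secrets; defaults to label-derived placeholders.
#' @return An event-log tibble (see [replay_log()]), including unrecorded
#'   identification events flagged `recorded = FALSE`.
#' @export
simulate_staff <- function(visits, behaviour, seed, policy = NULL, secrets = NULL) {
  n <- nrow(visits)
  if (n == 0L) {
    return(empty_log())
  }
  visits <- dplyr::arrange(visits, .data$timestamp)
  if (is.null(secrets)) {
    pids <- unique(visits$practice_id)
    secrets <- stats::setNames(paste0("secret-", pids), pids)
  }
  key <- paste(visits$practice_id, visits$internal_id, sep = "\r")
  ukey <- unique(key)
  pid <- match(key, ukey)
  first_of <- !duplicated(pid)
  sid_by_patient <- character(length(ukey))
  upr <- sub("\r.*$", "", ukey)
  for (p in unique(upr)) {
    i <- upr == p
    sid_by_patient[i] <- pseudonymize(sub("^.*\r", "", ukey[i]), secrets[[p]])
  }
  study_id <- sid_by_patient[pid]

  set.seed(seed)
  U <- matrix(stats::runif(4L * n), n, 4L)
  ridx <- sample(c("psychiatric_disorder", "language_barrier", "other"), n, replace = TRUE)

  sidx <- match(visits$stratum, cta_strata)
  mult <- rep(1, n)
  if (!is.null(behaviour$contact_multipliers)) {
    m <- behaviour$contact_multipliers[visits$stratum]
    mult <- ifelse(is.na(m), 1, unname(m))
  }
  p_resp <- pmin(behaviour$p_respond * mult, 1)
  p_excl <- behaviour$p_exclude_given_respond
  p_ref <- behaviour$p_refuse_given_contact
  p_int <- behaviour$p_interrupt_given_start

  use_policy <- !is.null(policy)
  tol <- if (use_policy) policy$tolerance else NA_real_
  min_enr <- if (use_policy) policy$min_enrolled else NA_real_
  net_cnt <- numeric(5L)
  enr_cnt <- numeric(5L)
  suppressed <- rep(FALSE, 5L)
  dirty <- FALSE

  state <- integer(length(ukey)) # 0 OPEN, 1 SIP, 2 EXCL, 3 REF, 4 ENR, 5 DEC
  identified <- logical(length(ukey))
  kinds <- vector("list", n)
  reason <- rep(NA_character_, n)
  recd <- visits$recorded
  dead <- visits$deceased
  present <- visits$physically_present

  for (i in seq_len(n)) {
    ev <- "epr_open"
    if (recd[i]) {
      p <- pid[i]
      s <- sidx[i]
      if (!identified[p]) {
        identified[p] <- TRUE
        net_cnt[s] <- net_cnt[s] + 1
        dirty <- TRUE
      }
      st <- state[p]
      if (st <= 1L) {
        alert <- TRUE
        if (use_policy) {
          if (dirty) {
            if (sum(enr_cnt) >= min_enr) {
              excess <- 100 * (enr_cnt / sum(enr_cnt) - net_cnt / sum(net_cnt))
              suppressed <- excess > tol
            } else {
              suppressed <- rep(FALSE, 5L)
            }
            dirty <- FALSE
          }
          alert <- !suppressed[s]
        }
        if (alert) {
          if (st == 0L) {
            if (U[i, 1L] >= p_resp[i]) {
              ev <- c(ev, "click_off")
            } else if (dead[i]) {
              ev <- c(ev, "deceased_noted")
              state[p] <- 5L
            } else if (U[i, 2L] < p_excl) {
              ev <- c(ev, "exclude")
              reason[i] <- if (!present[i]) "not_physically_present" else ridx[i]
              state[p] <- 2L
            } else if (U[i, 3L] < p_ref) {
              ev <- c(ev, "contact", "refuse")
              state[p] <- 3L
            } else if (U[i, 4L] < p_int) {
              ev <- c(ev, "contact", "consent", "survey_start", "survey_interrupt")
              state[p] <- 1L
            } else {
              ev <- c(ev, "contact", "consent", "survey_start", "survey_complete")
              state[p] <- 4L
              enr_cnt[s] <- enr_cnt[s] + 1
              dirty <- TRUE
            }
          } else { # survey in progress: resume
            if (U[i, 4L] < p_int) {
              ev <- c(ev, "survey_interrupt")
            } else {
              ev <- c(ev, "survey_complete")
              state[p] <- 4L
              enr_cnt[s] <- enr_cnt[s] + 1
              dirty <- TRUE
            }
          }
        }
      }
    }
    kinds[[i]] <- ev
  }

  n_ev <- lengths(kinds)
  off <- unlist(lapply(n_ev, seq_len), use.names = FALSE) - 1L
  i_rep <- rep(seq_len(n), n_ev)
  log <- tibble::tibble(
    timestamp = visits$timestamp[i_rep] + off * 60,
    practice_id = visits$practice_id[i_rep],
    study_id = study_id[i_rep],
    kind = unlist(kinds, use.names = FALSE),
    sex = visits$sex[i_rep],
    age_band = visits$stratum[i_rep],
    payload = NA_character_,
    recorded = recd[i_rep]
  )
  log$payload[log$kind == "exclude"] <- reason[!is.na(reason)]
  # follow-up events sit minutes after their visit; re-sort so timestamps are
  # non-decreasing within every practice (the log-file invariant)
  dplyr::arrange(log, .data$timestamp)
}

#' Simulate a whole multi-practice study
#'
#' Generates panels and visit streams independently per practice (random
#' streams keyed by the master seed and the practice label), then runs one
#' global staff-decision pass over the merged, time-ordered visit stream, so
#' that an adaptive suppression policy — which pools registry counts at the
#' study centre — acts across practices.
#'
#' @param practices A list of [practice_config()] objects (unique labels).
#' @param behaviour A [staff_behaviour()].
#' @param seed Master integer seed.
#' @param policy Optional [suppression_policy()].
#' @return A list with elements `log` (the full event log, unrecorded
#'   identification events included), `panel` (all patient records) and
#'   `visits`.
#' @export
simulate_study <- function(practices, behaviour = staff_behaviour(), seed = 1,
                           policy = NULL) {
  ids <- vapply(practices, function(p) p$practice_id, character(1))
  if (anyDuplicated(ids)) {
    rlang::abort("practice labels must be unique", class = "cta_config_error")
  }
  panels <- purrr::map(practices, function(cfg) {
    generate_panel(cfg, derive_seed(seed, cfg$practice_id, "panel"))
  })
  visits <- purrr::map2_dfr(practices, panels, function(cfg, panel) {
    simulate_visits(panel, cfg, derive_seed(seed, cfg$practice_id, "visits"))
  })
  visits <- dplyr::arrange(visits, .data$timestamp)
  secrets <- stats::setNames(
    vapply(practices, function(p) p$practice_secret, character(1)), ids
  )
  log <- simulate_staff(
    visits, behaviour,
    seed = derive_seed(seed, "all", "staff"),
    policy = policy, secrets = secrets
  )
  list(log = log, panel = dplyr::bind_rows(panels), visits = visits)
}

#' Registry view of an event log
#'
#' Drops events that fell into software downtime (`recorded = FALSE`): what
#' the study-centre registry actually received.
#'
#' @param log An event-log tibble.
#' @return The recorded subset.
#' @export
registry_view <- function(log) {
  if (!"recorded" %in% names(log)) {
    return(log)
  }
  dplyr::filter(log, .data$recorded)
}

#' Oracle view of an event log
#'
#' All identification (`epr_open`) events, recorded or not: the ground truth
#' a full practice-database query would return. Always a superset of the
#' registry's identifications.
#'
#' @param log An event-log tibble.
#' @return The `epr_open` subset, including unrecorded events.
#' @export
oracle_view <- function(log) {
  dplyr::filter(log, .data$kind == "epr_open")
}

# deterministic per-practice sub-seed below 2^31, keyed by (master seed, label)
derive_seed <- function(master, label, role) {
  h <- digest::digest(paste(master, label, role, sep = "/"), algo = "sha256")
  strtoi(substr(h, 1L, 7L), base = 16L)
}

empty_log <- function() {
  tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    practice_id = character(), study_id = character(), kind = character(),
    sex = character(), age_band = character(), payload = character(),
    recorded = logical()
  )
}
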