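# build a tiny event log for one record: `kinds` in visit order, all on the
# same day unless `days` is given per event
record_log <- function(study_id, kinds, reason = NA_character_,
                       practice_id = "P1", sex = "F", band = "F60-69",
                       day = as.Date("2007-06-01"), days = NULL,
                       recorded = TRUE) {
  if (is.null(days)) days <- rep(day, length(kinds))
  tibble::tibble(
    timestamp = as.POSIXct(paste(days, "09:00:00"), tz = "UTC") +
      seq_along(kinds) * 60,
    practice_id = practice_id,
    study_id = study_id,
    kind = kinds,
    sex = sex,
    age_band = band,
    payload = ifelse(kinds == "exclude", reason, NA_character_),
    recorded = recorded
  )
}

# independent brute-force Pearson chi-square on a 2 x k table
pearson_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(
    statistic = sum((tab - expected)^2 / expected),
    df = as.integer((nrow(tab) - 1L) * (ncol(tab) - 1L))
  )
}

# a small simulated study log for property tests
small_sim <- function(seed, panel_size = 40, visit_rate = 0.4,
                      behaviour = staff_behaviour(p_respond = 0.3),
                      policy = NULL, practices = 1) {
  cfgs <- lapply(seq_len(practices), function(i) {
    practice_config(sprintf("SP%02d", i), panel_size, visit_rate = visit_rate)
  })
  simulate_study(cfgs, behaviour, seed = seed, policy = policy)
}

# stage/stratum counts as a named-vector lookup from a cta_strata tibble
strata_counts <- function(strata, stage) {
  s <- strata[strata$stage == stage, ]
  stats::setNames(s$n, s$stratum)
}
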