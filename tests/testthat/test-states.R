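test_that("the transition table matches the recruitment protocol", {
  cases <- list(
    c("OPEN", "epr_open", "OPEN"),
    c("OPEN", "click_off", "OPEN"), # reminder will re-fire at the next opening
    c("OPEN", "exclude", "EXCLUDED"),
    c("OPEN", "contact", "OPEN"),
    c("OPEN", "refuse", "REFUSED"),
    c("OPEN", "consent", "OPEN"),
    c("OPEN", "survey_start", "SURVEY_IN_PROGRESS"),
    c("OPEN", "deceased_noted", "DECEASED"),
    c("SURVEY_IN_PROGRESS", "epr_open", "SURVEY_IN_PROGRESS"),
    c("SURVEY_IN_PROGRESS", "survey_interrupt", "SURVEY_IN_PROGRESS"),
    c("SURVEY_IN_PROGRESS", "survey_complete", "ENROLLED")
  )
  for (c in cases) {
    expect_identical(apply_event(c[1], c[2]), c[3])
  }
})

test_that("terminal states absorb: only a plain EPR opening is tolerated", {
  for (st in c("EXCLUDED", "REFUSED", "ENROLLED", "DECEASED")) {
    expect_identical(apply_event(st, "epr_open"), st)
    for (k in setdiff(cta_event_kinds, "epr_open")) {
      expect_error(apply_event(st, k), class = "cta_terminal_state")
    }
  }
})

test_that("out-of-order events raise protocol errors", {
  expect_error(apply_event("OPEN", "survey_complete"), class = "cta_protocol_error")
  expect_error(apply_event("OPEN", "survey_interrupt"), class = "cta_protocol_error")
  expect_error(apply_event("SURVEY_IN_PROGRESS", "contact"), class = "cta_protocol_error")
  expect_error(apply_event("OPEN", "not_a_kind"), class = "cta_protocol_error")
})

test_that("replay folds legal sequences to the expected final states", {
  log <- dplyr::bind_rows(
    record_log("A", c("epr_open", "click_off")),
    record_log("B", c("epr_open", "exclude"), reason = "psychiatric_disorder"),
    record_log("C", c("epr_open", "contact", "refuse")),
    record_log("D", c("epr_open", "contact", "consent", "survey_start", "survey_complete")),
    record_log("E", c("epr_open", "contact", "consent", "survey_start", "survey_interrupt")),
    record_log("F", c("epr_open", "deceased_noted"))
  )
  reg <- replay_log(log)
  expect_identical(
    stats::setNames(reg$state, reg$study_id),
    c(A = "OPEN", B = "EXCLUDED", C = "REFUSED", D = "ENROLLED",
      E = "SURVEY_IN_PROGRESS", F = "DECEASED")
  )
  expect_identical(reg$exclusion_reason[reg$study_id == "B"], "psychiatric_disorder")
  # an interrupted survey resumes on a later day and completes
  log2 <- dplyr::bind_rows(
    record_log("E", c("epr_open", "contact", "consent", "survey_start", "survey_interrupt")),
    record_log("E", c("epr_open", "survey_complete"), day = as.Date("2007-06-20"))
  )
  expect_identical(replay_log(log2)$state, "ENROLLED")
})

test_that("replay is deterministic and idempotent on simulated logs", {
  log <- small_sim(11)$log
  expect_identical(replay_log(log), replay_log(log))
})

test_that("replay enforces the event protocol", {
  # first event not an identification
  expect_error(replay_log(record_log("A", "click_off")), class = "cta_protocol_error")
  # recruitment event on a different day than the EPR opening
  bad <- record_log("A", c("epr_open", "contact", "refuse"),
                    days = as.Date(c("2007-06-01", "2007-06-02", "2007-06-02")))
  expect_error(replay_log(bad), class = "cta_protocol_error")
  # refusal without a contact
  expect_error(replay_log(record_log("A", c("epr_open", "refuse"))),
               class = "cta_protocol_error")
  # exclusion without a reason
  expect_error(replay_log(record_log("A", c("epr_open", "exclude"))),
               class = "cta_protocol_error")
  # event after enrolment
  done <- record_log("A", c("epr_open", "contact", "consent", "survey_start",
                            "survey_complete", "contact"))
  expect_error(replay_log(done), class = "cta_terminal_state")
})

test_that("unrecorded (downtime) events are invisible to the registry", {
  log <- dplyr::bind_rows(
    record_log("A", "epr_open", recorded = FALSE),
    record_log("B", c("epr_open", "click_off"))
  )
  reg <- replay_log(log)
  expect_identical(reg$study_id, "B")
})

test_that("alerts fire for open and in-progress records only", {
  expect_true(should_alert("OPEN"))
  expect_true(should_alert("SURVEY_IN_PROGRESS"))
  for (st in c("EXCLUDED", "REFUSED", "ENROLLED", "DECEASED")) {
    expect_false(should_alert(st))
  }
})

test_that("alerts respect the suppression policy, consistently with its update rule", {
  strata <- tibble::tibble(
    stage = rep(c("net_sample", "enrolled"), each = 5),
    stratum = rep(cta_strata, 2),
    n = c(292, 324, 384, 564, 436, # net shares
          376, 419, 206, 706, 294) # enrolled shares: F60-69 and M70-79 in excess
  )
  pol <- update_suppression(suppression_policy(tolerance = 5, min_enrolled = 50), strata)
  expect_true(length(pol$suppressed_strata) > 0)
  for (s in cta_strata) {
    expect_identical(
      should_alert("OPEN", s, pol),
      !s %in% pol$suppressed_strata
    )
  }
  # terminal state never alerts, suppressed or not
  expect_false(should_alert("ENROLLED", pol$suppressed_strata[1], pol))
})
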