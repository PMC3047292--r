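test_that("panel generation honours size, seed and demography", {
  cfg <- practice_config("P1", 0)
  expect_identical(nrow(generate_panel(cfg, 1)), 0L)

  cfg <- practice_config("P1", 16067)
  panel <- generate_panel(cfg, 42)
  expect_identical(generate_panel(cfg, 42), panel) # reproducible
  # women share within 3 binomial SE of the configured 72.0%
  p <- 0.72
  se <- sqrt(p * (1 - p) / nrow(panel))
  expect_lt(abs(mean(panel$sex == "F") - p), 3 * se)
  # every patient is in the net sample at study start, in the drawn band
  expect_identical(
    age_band(panel$sex, panel$birth_date, cfg$study_start),
    panel$stratum
  )
})

test_that("stratum counts are consistent with the configured demography across seeds", {
  cfg <- practice_config("P1", 2000)
  rejections <- vapply(1:100, function(seed) {
    panel <- generate_panel(cfg, seed)
    obs <- table(factor(panel$stratum, levels = cta_strata))
    p <- suppressWarnings(stats::chisq.test(obs, p = cfg$demography)$p.value)
    p < 0.01
  }, logical(1))
  # at alpha = 0.01 the rejection rate should be about 1%
  expect_lte(sum(rejections), 5L)
})

test_that("a bad demography vector is rejected", {
  dem <- cta_net_demography()
  expect_error(practice_config("P1", 10, demography = dem * 1.01),
               class = "cta_config_error")
  expect_error(practice_config("P1", 10, demography = dem[-1]),
               class = "cta_config_error")
})

test_that("visit counts are Poisson with the configured mean", {
  cfg0 <- practice_config("P1", 100, visit_rate = 0)
  expect_identical(nrow(simulate_visits(generate_panel(cfg0, 1), cfg0, 2)), 0L)

  cfg <- practice_config("P1", 1000, visit_rate = 1.0, study_months = 12)
  visits <- simulate_visits(generate_panel(cfg, 1), cfg, 2)
  expect_lt(abs(nrow(visits) - 12000), 3 * sqrt(12000))
  expect_false(is.unsorted(visits$timestamp))
})

test_that("downtime hides events from the registry but not the oracle", {
  cfg <- practice_config(
    "P1", 200, visit_rate = 0.5,
    downtime_windows = list(c("2007-05-01", "2008-04-30"))
  )
  sim <- simulate_study(list(cfg), staff_behaviour(), seed = 3)
  expect_identical(nrow(registry_view(sim$log)), 0L)
  expect_gt(nrow(oracle_view(sim$log)), 0L)
  expect_identical(nrow(oracle_view(sim$log)), nrow(sim$visits))
  # windows outside the study period are rejected
  expect_error(
    practice_config("P1", 10, downtime_windows = list(c("2006-01-01", "2006-02-01"))),
    class = "cta_config_error"
  )
})

test_that("unresponsive staff leave every record open", {
  cfg <- practice_config("P1", 300, visit_rate = 0.5)
  sim <- simulate_study(list(cfg), staff_behaviour(p_respond = 0), seed = 7)
  reg <- replay_log(sim$log)
  expect_true(all(reg$state == "OPEN"))
  expect_setequal(unique(sim$log$kind), c("epr_open", "click_off"))
})

test_that("a configured refusal probability is recovered from the log", {
  cfg <- practice_config("P1", 11000, visit_rate = 0.25, deceased_frac = 0)
  beh <- staff_behaviour(
    p_respond = 0.9, p_exclude_given_respond = 0,
    p_refuse_given_contact = 0.30, p_interrupt_given_start = 0
  )
  sim <- simulate_study(list(cfg), beh, seed = 101)
  f <- funnel_counts(registry_view(sim$log))
  expect_gte(f$contacted, 10000L)
  se <- sqrt(0.3 * 0.7 / f$contacted)
  expect_lt(abs(f$refused / f$contacted - 0.30), 3 * se)
})

test_that("same seed gives a bit-identical log; simulated logs replay legally", {
  a <- small_sim(5, panel_size = 80)
  b <- small_sim(5, panel_size = 80)
  expect_identical(a$log, b$log)
  expect_silent(reg <- replay_log(a$log))
  # staff behaviour never violates the state machine across seeds
  for (seed in 1:10) {
    expect_silent(replay_log(small_sim(seed)$log))
  }
})

test_that("unbiased staff enrol a sample matching the net demography; biased staff do not", {
  cfg <- practice_config("P1", 4000, visit_rate = 0.25, deceased_frac = 0)
  beh <- staff_behaviour(
    p_respond = 0.5, p_exclude_given_respond = 0.1, p_refuse_given_contact = 0.1
  )
  sim <- simulate_study(list(cfg), beh, seed = 9)
  strata <- stage_demography(registry_view(sim$log))
  net <- strata_counts(strata, "net_sample")
  enr <- strata_counts(strata, "enrolled")
  expect_gt(sum(enr), 2000)
  expect_lt(tv_distance(enr, net), 0.05)

  biased <- staff_behaviour(
    p_respond = 0.5, p_exclude_given_respond = 0.1, p_refuse_given_contact = 0.1,
    contact_multipliers = c("F60-69" = 3, "F80+" = 0.3, "M80+" = 0.3)
  )
  simb <- simulate_study(list(cfg), biased, seed = 9)
  sb <- stage_demography(registry_view(simb$log))
  expect_gt(representation_ratio(sb, "F60-69"), 1)
  expect_gt(
    tv_distance(strata_counts(sb, "enrolled"), strata_counts(sb, "net_sample")),
    tv_distance(enr, net)
  )
})
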