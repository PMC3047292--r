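test_that("stage demography reproduces the reference enrolment shares", {
  strata <- stage_demography(cta_reference_log())
  enr <- strata[strata$stage == "enrolled", ]
  expect_identical(sum(enr$n[enr$sex == "F"]), 1240L)
  dem <- demography_table(strata)
  expect_identical(dem$enrolled[dem$label == "Women"], 81.3)
  expect_identical(dem$enrolled[dem$label == "Men"], 18.7)
})

test_that("a single-stratum log yields a 100% share and stages sum to ~100", {
  log <- record_log("A", c("epr_open", "click_off"), sex = "M", band = "M80+")
  strata <- stage_demography(log)
  expect_identical(strata$pct[strata$stage == "open" & strata$stratum == "M80+"], 100)
  sums <- tapply(stage_demography(cta_reference_log())$pct,
                 stage_demography(cta_reference_log())$stage, sum)
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("the chi-square statistic equals a brute-force Pearson oracle to 1e-9", {
  tables <- list(
    list(net = c(F = 11574, M = 4493), enr = c(F = 1240, M = 286)),
    list(net = c(3377, 3748, 4449), enr = c(466, 519, 255)),   # women age bands
    list(net = c(2536, 1957), enr = c(202, 84)),               # men age bands
    list(net = c(120, 80, 50, 200), enr = c(12, 40, 5, 21))
  )
  for (tb in tables) {
    for (mode in c("enrolled_vs_rest", "enrolled_vs_net")) {
      res <- chi_square_bias_test(tb$net, tb$enr, mode = mode)
      other <- if (mode == "enrolled_vs_rest") tb$net - tb$enr else tb$net
      oracle <- pearson_oracle(rbind(tb$enr, other))
      expect_lt(abs(res$statistic - oracle$statistic), 1e-9)
      expect_identical(res$df, oracle$df)
      expect_gte(res$statistic, 0)
      expect_identical(
        res$p_value,
        stats::pchisq(res$statistic, res$df, lower.tail = FALSE)
      )
    }
  }
})

test_that("identical group proportions give statistic 0 and p = 1", {
  res <- chi_square_bias_test(c(100, 200, 400), c(25, 50, 100),
                              mode = "enrolled_vs_net")
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
  # 2 x 3 table has 2 degrees of freedom
  expect_identical(res$df, 2L)
})

test_that("degenerate and invalid tables are rejected", {
  expect_error(chi_square_bias_test(c(10, 0), c(5, 0)), class = "cta_degenerate_table")
  expect_error(chi_square_bias_test(c(10, 20), c(11, 5)), class = "cta_invalid_input")
  expect_error(chi_square_bias_test(c(10, 20), c(5, -1)), class = "cta_invalid_input")
  expect_error(chi_square_bias_test(c(10, 20, 30), c(5, 5)), class = "cta_invalid_input")
})

test_that("tidy and glance return one-row summaries", {
  res <- chi_square_bias_test(c(F = 11574, M = 4493), c(F = 1240, M = 286))
  td <- generics::tidy(res)
  expect_identical(nrow(td), 1L)
  expect_named(td, c("statistic", "df", "p.value", "method"))
  expect_identical(generics::glance(res)$statistic, res$statistic)
})

test_that("representation ratios match hand arithmetic on the reference counts", {
  strata <- cta_reference_strata()
  sex_tab <- tibble::tibble(
    stage = rep(c("net_sample", "enrolled"), each = 2),
    stratum = rep(c("F", "M"), 2),
    n = c(11574, 4493, 1240, 286)
  )
  expect_equal(representation_ratio(sex_tab, "M"),
               (286 / 1526) / (4493 / 16067), tolerance = 1e-12)
  women <- strata[strata$sex == "F", ]
  expect_equal(representation_ratio(women, "F80+"), 0.536, tolerance = 0.01)
  # proportional enrolment gives ratio 1 in every stratum
  prop <- tibble::tibble(
    stage = rep(c("net_sample", "enrolled"), each = 2),
    stratum = rep(c("F", "M"), 2), n = c(720, 280, 72, 28)
  )
  expect_equal(unname(representation_ratio(prop)), c(1, 1))
  # scale invariance
  big <- sex_tab; big$n <- big$n * 7
  expect_identical(representation_ratio(big), representation_ratio(sex_tab))
  expect_error(
    representation_ratio(sex_tab, "X"), class = "cta_undefined_ratio"
  )
})

test_that("registry overlap is the captured fraction of the oracle", {
  expect_identical(registry_consistency(c("a", "b"), c("a", "b")), 1)
  expect_identical(registry_consistency(c("a", "b"), c("c", "d")), 0)
  expect_identical(registry_consistency(character(), c("a")), 0)
  expect_error(registry_consistency(c("a"), character()), class = "cta_invalid_input")
})

test_that("downtime lowers registry overlap by the expected missingness", {
  # Poisson(1.5) visits per patient, a downtime window covering ~20% of the
  # study: a patient is missed iff all visits fall inside the window, so the
  # expected capture is 1 - exp(-lambda) (exp(lambda*f) - 1) / (1 - exp(-lambda))
  lambda <- 1.5
  f <- 73 / 366
  expected <- 1 - exp(-lambda) * (expm1(lambda * f)) / (-expm1(-lambda))
  cfg <- practice_config(
    "P1", 300, visit_rate = lambda / 12,
    downtime_windows = list(c("2007-05-01", "2007-07-12"))
  )
  overlaps <- vapply(1:50, function(seed) {
    sim <- simulate_study(list(cfg), staff_behaviour(), seed = seed)
    oracle_ids <- unique(oracle_view(sim$log)$study_id)
    registry_ids <- unique(registry_view(sim$log)$study_id)
    registry_consistency(registry_ids, oracle_ids)
  }, numeric(1))
  se <- stats::sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - expected), 3 * se)
})

test_that("suppression activates on excess representation and releases on balance", {
  mk <- function(enr) tibble::tibble(
    stage = rep(c("net_sample", "enrolled"), each = 5),
    stratum = rep(cta_strata, 2),
    n = c(c(2104, 2333, 2765, 1579, 1219) * 10, enr)
  )
  pol <- suppression_policy(tolerance = 5, min_enrolled = 50)
  # enrolled shares equal to net shares: nothing suppressed
  expect_length(update_suppression(pol, mk(c(2104, 2333, 2765, 1579, 1219)))$suppressed_strata, 0)
  # women 60-69 enrolled at 37.6% against a 29.2% net share within women:
  # an 8.4-point excess beyond the 5-point tolerance
  women <- tibble::tibble(
    stage = rep(c("net_sample", "enrolled"), each = 3),
    stratum = rep(c("F60-69", "F70-79", "F80+"), 2),
    n = c(3377, 3748, 4449, 466, 519, 255)
  )
  pol2 <- update_suppression(pol, women)
  expect_true("F60-69" %in% pol2$suppressed_strata)
  expect_false("F80+" %in% pol2$suppressed_strata)
  # the suppressed stratum is released once its excess falls within tolerance
  balanced <- tibble::tibble(
    stage = rep(c("net_sample", "enrolled"), each = 3),
    stratum = rep(c("F60-69", "F70-79", "F80+"), 2),
    n = c(3377, 3748, 4449, 300, 320, 380)
  )
  expect_length(update_suppression(pol2, balanced)$suppressed_strata, 0)
  # below min_enrolled nothing activates
  tiny <- women; tiny$n[4:6] <- c(30, 5, 5)
  expect_length(update_suppression(pol, tiny)$suppressed_strata, 0)
})
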