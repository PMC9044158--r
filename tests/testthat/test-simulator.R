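test_that("frequency categories map to the documented daily rates", {
  expect_equal(frequency_rate("weekly"), 1 / 7)
  expect_equal(round(frequency_rate("weekly"), 4), 0.1429)
  expect_equal(round(frequency_rate("monthly"), 4), 0.0333)
  expect_equal(frequency_rate("multiple/day"), 0.95)
  expect_equal(frequency_rate("daily"), 0.80)
  expect_equal(frequency_rate("every few months"), 1 / 90)
  expect_equal(frequency_rate("less"), 1 / 240)
  expect_error(frequency_rate("fortnightly"), "unknown recurrence-frequency")
})

test_that("scenario validation rejects impossible probabilities", {
  expect_error(nof1_scenario(30, 1.2), "base_rate")
  expect_error(nof1_scenario(30, 0.5,
                             data.frame(name = "f", exposure_prob = 0.5,
                                        lag = 0L, effect = 0.7)),
               "\\[0, 1\\]")
  expect_error(nof1_scenario(30, 0.5,
                             data.frame(name = "f", exposure_prob = 1.5,
                                        lag = 0L, effect = 0)),
               "exposure")
  expect_error(nof1_scenario(30, 0.5,
                             data.frame(name = "f", exposure_prob = 0.5,
                                        lag = 2L, effect = 0)),
               "lags")
})

test_that("degenerate scenarios simulate exactly as specified", {
  d0 <- simulate_diary(nof1_scenario(50, 0, seed = 5))
  expect_equal(sum(d0$entries$outcome), 0)
  d1 <- simulate_diary(nof1_scenario(100, 0.3, adherence = 1, seed = 5))
  expect_equal(nrow(d1$entries), 100)
  expect_equal(as.numeric(diff(range(d1$entries$date))), 99)
})

test_that("the empirical event rate matches the scenario base rate", {
  d <- simulate_diary(nof1_scenario(5000, 0.3, seed = 88))
  rate <- mean(d$entries$outcome)
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
})

test_that("adherence thins the diary at the expected rate", {
  d <- simulate_diary(nof1_scenario(4000, 0.2, adherence = 0.7, seed = 12))
  expect_lt(abs(nrow(d$entries) / 4000 - 0.7), 3 * sqrt(0.7 * 0.3 / 4000))
  # dates remain strictly increasing with gaps
  expect_true(all(diff(d$entries$date) >= 1))
})

test_that("identical scenario and seed give byte-identical diary files", {
  sc <- nof1_scenario(60, 0.25,
                      data.frame(name = "f", exposure_prob = 0.4, lag = 1L,
                                 effect = 0.3),
                      adherence = 0.85, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_diary(simulate_diary(sc), f1)
  write_diary(simulate_diary(sc), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_diary(nof1_scenario(30, 0.2, seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("a lag-1 effect expresses at lag 1, not lag 0", {
  sc <- nof1_scenario(3000, 0.2,
                      data.frame(name = "trig", exposure_prob = 0.5,
                                 lag = 1L, effect = 0.4),
                      seed = 303)
  d <- simulate_diary(sc)
  phi1 <- phi_coef(build_contingency(d, "outcome", "trig", 1))
  phi0 <- phi_coef(build_contingency(d, "outcome", "trig", 0))
  expect_gt(phi1, 0.3)
  expect_lt(abs(phi0), 0.1)
})

test_that("odds-ratio effects raise the event rate on exposed days", {
  sc <- nof1_scenario(4000, 0.2,
                      data.frame(name = "f", exposure_prob = 0.5, lag = 0L,
                                 effect = 4),
                      seed = 21, effect_scale = "odds_ratio")
  d <- simulate_diary(sc)
  e <- d$entries
  rate_exp <- mean(e$outcome[e$f == 1])
  rate_unexp <- mean(e$outcome[e$f == 0])
  expected <- plogis(qlogis(0.2) + log(4))
  expect_lt(abs(rate_unexp - 0.2), 0.03)
  expect_lt(abs(rate_exp - expected), 0.03)
})

test_that("the simulate generic yields independent reproducible replicates", {
  sc <- nof1_scenario(20, 0.3, seed = 14)
  ds <- simulate(sc, nsim = 3)
  expect_length(ds, 3)
  expect_false(identical(ds[[1]]$entries$outcome, ds[[2]]$entries$outcome))
  ds2 <- simulate(sc, nsim = 3)
  expect_identical(lapply(ds, `[[`, "entries"), lapply(ds2, `[[`, "entries"))
})

test_that("power estimation is reproducible and reports its MC error", {
  sc <- nof1_scenario(60, 0.2,
                      data.frame(name = "trig", exposure_prob = 0.5,
                                 lag = 1L, effect = 0.4),
                      seed = 500)
  pw <- estimate_power(sc, n_reps = 100)
  expect_s3_class(pw, "nof1_power")
  expect_equal(pw$mc_se,
               sqrt(pw$detect_rate * (1 - pw$detect_rate) / pw$n_reps))
  pw2 <- estimate_power(sc, n_reps = 100)
  expect_identical(pw$detect_rate, pw2$detect_rate)
})

test_that("power rises with effect size and horizon", {
  mk <- function(n_days, effect) {
    nof1_scenario(n_days, 0.2,
                  data.frame(name = "trig", exposure_prob = 0.5, lag = 1L,
                             effect = effect),
                  seed = 611)
  }
  rule <- detection_rule("trig", lag = 1)
  p_null <- estimate_power(mk(90, 0), n_reps = 150, rule = rule)
  p_mid <- estimate_power(mk(90, 0.3), n_reps = 150, rule = rule)
  p_big <- estimate_power(mk(90, 0.5), n_reps = 150, rule = rule)
  tol <- 2 * sqrt(0.25 / 150)
  expect_lte(p_null$detect_rate, p_mid$detect_rate + tol)
  expect_lte(p_mid$detect_rate, p_big$detect_rate + tol)
  expect_gt(p_big$detect_rate, p_null$detect_rate)
  p_short <- estimate_power(mk(14, 0.4), n_reps = 150, rule = rule)
  p_long <- estimate_power(mk(90, 0.4), n_reps = 150, rule = rule)
  expect_lte(p_short$detect_rate, p_long$detect_rate + tol)
})

test_that("detection rules validate their target factor", {
  sc <- nof1_scenario(30, 0.2,
                      data.frame(name = "trig", exposure_prob = 0.5,
                                 lag = 1L, effect = 0.4),
                      seed = 3)
  expect_error(estimate_power(sc, n_reps = 100,
                              rule = detection_rule("ghost", 1)),
               "unknown factor")
})

test_that("threshold calibration reports an achieved level at most alpha", {
  sc <- nof1_scenario(60, 0.3,
                      data.frame(name = "f", exposure_prob = 0.5, lag = 0L,
                                 effect = 0),
                      seed = 40)
  cal <- calibrate_phi_threshold(sc, "f", lag = 0, alpha = 0.1,
                                 n_reps = 300)
  expect_lte(cal$alpha_achieved, 0.1)
  expect_gt(cal$threshold, 0)
})
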