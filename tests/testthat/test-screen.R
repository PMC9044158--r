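test_that("a two-day diary yields only insufficient-tier rows", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:1,
                        o = c(1L, 0L), f = c(1L, 0L)),
             roles = c(o = "outcome", f = "factor"))
  scr <- nof1_screen(d)
  expect_true(all(scr$tier == "insufficient"))
  expect_true(all(is.na(scr$phi)))
  expect_match(scr$reason, "insufficient data", all = TRUE)
})

test_that("screening starts at three complete pairs", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:2,
                        o = c(1L, 0L, 1L), f = c(1L, 0L, 1L)),
             roles = c(o = "outcome", f = "factor"))
  scr <- nof1_screen(d)
  lag0 <- scr[scr$lag == 0, ]
  expect_equal(lag0$tier, "low")
  expect_equal(lag0$phi, 1)
  # lag 1 has only 2 pairs -> still insufficient
  expect_equal(scr$tier[scr$lag == 1], "insufficient")
})

test_that("a strong lag-1 trigger ranks first in a simulated diary", {
  sc <- nof1_scenario(
    n_days = 60, base_rate = 0.2,
    factors = data.frame(name = c("trigger", "noise"),
                         exposure_prob = c(0.5, 0.5),
                         lag = c(1L, 0L), effect = c(0.5, 0)),
    seed = 2024
  )
  scr <- nof1_screen(simulate_diary(sc))
  expect_equal(scr$factor[1], "trigger")
  expect_equal(scr$lag[1], 1L)
  expect_gt(abs(scr$phi[1]), 0.3)
})

test_that("a constant factor column reports an undefined phi with reason", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:9,
                        o = rep(c(0L, 1L), 5), f = rep(0L, 10)),
             roles = c(o = "outcome", f = "factor"))
  scr <- nof1_screen(d)
  expect_true(all(is.na(scr$phi)))
  expect_match(scr$reason, "no variation in factor", all = TRUE)
  expect_equal(scr$tier[scr$lag == 0], "low")  # tier reflects pair count
})

test_that("undefined phi sorts after all defined results", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:19,
                        o = rep(c(0L, 1L), 10),
                        const = rep(0L, 20),
                        varies = rep(c(1L, 0L), 10)),
             roles = c(o = "outcome", const = "factor", varies = "factor"))
  scr <- nof1_screen(d)
  defined <- !is.na(scr$phi)
  expect_true(all(which(defined) < which(!defined)))
})

test_that("the screen is deterministic and ties break by n_days then name", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:29,
                        o = rep(c(0L, 1L), 15),
                        b = rep(c(0L, 1L), 15),
                        a = rep(c(0L, 1L), 15)),
             roles = c(o = "outcome", a = "factor", b = "factor"))
  scr1 <- nof1_screen(d)
  scr2 <- nof1_screen(d)
  expect_identical(scr1, scr2)
  # equal phi and n_days at lag 0: lexicographic factor order
  lag0 <- scr1[scr1$lag == 0, ]
  expect_equal(lag0$factor, c("a", "b"))
  # lag 0 has 30 pairs, lag 1 has 29: lag 0 rows first within equal phi
  expect_true(all(diff(scr1$n_days[!is.na(scr1$phi)]) <= 0))
})

test_that("tier boundaries follow the documented thresholds", {
  th <- tier_thresholds()
  expect_equal(as.character(assign_tier(c(0, 2, 3, 13, 14, 29, 30, 100), th)),
               c("insufficient", "insufficient", "low", "low", "moderate",
                 "moderate", "high", "high"))
})

test_that("bonferroni adjustment multiplies across factors within outcome-lag", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:19,
                        o = rep(c(0L, 1L), 10),
                        f1 = rep(c(1L, 0L), 10),
                        f2 = c(rep(0L, 10), rep(1L, 10))),
             roles = c(o = "outcome", f1 = "factor", f2 = "factor"))
  scr <- nof1_screen(d, adjust = "bonferroni")
  expect_true(all(c("p", "p_adj") %in% names(scr)))
  expect_equal(scr$p_adj, pmin(1, scr$p * 2), tolerance = 1e-12)
})

test_that("screen serialisation carries 4-decimal phi in TSV and JSON", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:9,
                        o = c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L),
                        f = c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L)),
             roles = c(o = "outcome", f = "factor"))
  scr <- nof1_screen(d)
  tsv <- format_screen(scr, "tsv")
  expect_equal(tsv[1],
               paste(c("outcome", "factor", "lag", "phi", "n_days", "n11",
                       "n10", "n01", "n00", "tier", "reason"),
                     collapse = "\t"))
  expect_equal(length(tsv), nrow(scr) + 1)
  js <- jsonlite::fromJSON(format_screen(scr, "json"))
  expect_equal(nrow(js), nrow(scr))
  expect_equal(js$phi, as.numeric(sprintf("%.4f", scr$phi)))
})
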