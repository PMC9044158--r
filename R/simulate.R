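#' Daily event probability for a recurrence-frequency category
#'
#' Survey respondents describe how often their condition recurs in broad
#' categories; the simulator maps each category to a daily Bernoulli
#' probability. Categories slower than daily map to one event per period
#' (weekly -> 1/7 and so on). "Multiple times per day" cannot be expressed
#' in a daily-binary diary, so it collapses to a near-saturated daily
#' probability of 0.95 — deliberately not 1, but close enough that the
#' outcome column barely varies, which is precisely the regime in which
#' correlation screening loses power (a property the harness should
#' surface, not hide).
#'
#' @param category One of `"multiple/day"`, `"daily"`, `"weekly"`,
#'   `"monthly"`, `"every few months"`, `"less"`.
#' @return Daily event probability.
#' @examples
#' frequency_rate("weekly")   # 1/7
#' frequency_rate("monthly")  # 1/30
#' @export
frequency_rate <- function(category) {
  rates <- c("multiple/day" = 0.95, "daily" = 0.80, "weekly" = 1 / 7,
             "monthly" = 1 / 30, "every few months" = 1 / 90,
             "less" = 1 / 240)
  if (!is.character(category) || length(category) != 1 ||
      !category %in% names(rates)) {
    stop("unknown recurrence-frequency category: ",
         paste(category, collapse = ", "), "; must be one of ",
         paste(names(rates), collapse = ", "))
  }
  unname(rates[category])
}

#' Define a diary simulation scenario
#'
#' Describes the generative model for a synthetic N-of-1 diary: each
#' candidate factor is an independent daily Bernoulli exposure; the outcome
#' on day *t* is Bernoulli with probability `base_rate` plus the sum of
#' each factor's `risk_difference` whenever that factor was present at its
#' stated lag (same day for lag 0, previous day for lag 1), clipped to
#' \[0, 1\]. With `effect_scale = "odds_ratio"` the `effect` column is
#' instead an odds ratio applied multiplicatively on the odds scale. Days
#' are logged independently with probability `adherence`; unlogged days are
#' absent from the diary entirely (completely-at-random missingness).
#'
#' @param n_days Diary horizon in days.
#' @param base_rate Daily outcome probability in \[0, 1\], or a
#'   recurrence-frequency category accepted by [frequency_rate()].
#' @param factors Data frame with columns `name`, `exposure_prob`, `lag`
#'   (0 or 1) and `effect` (risk difference, or odds ratio under
#'   `effect_scale = "odds_ratio"`). May have zero rows for a null,
#'   factor-free outcome series; use `effect = 0` (or odds ratio 1) for a
#'   null factor that is still logged.
#' @param adherence Probability in (0, 1\] that a given day is logged.
#' @param seed Integer seed; simulation is fully deterministic given the
#'   scenario.
#' @param effect_scale `"risk_difference"` (additive on the probability
#'   scale, the default) or `"odds_ratio"`.
#' @param start Calendar date of day 1 (dates only matter through
#'   consecutiveness).
#' @return An object of class `nof1_scenario`.
#' @examples
#' sc <- nof1_scenario(
#'   n_days = 90, base_rate = 0.2,
#'   factors = data.frame(name = "trigger", exposure_prob = 0.5,
#'                        lag = 1, effect = 0.4),
#'   seed = 42
#' )
#' simulate_diary(sc)
#' @export
nof1_scenario <- function(n_days, base_rate, factors = NULL, adherence = 1,
                          seed = 1L,
                          effect_scale = c("risk_difference", "odds_ratio"),
                          start = as.Date("2020-01-01")) {
  effect_scale <- match.arg(effect_scale)
  if (is.character(base_rate)) base_rate <- frequency_rate(base_rate)
  stopifnot(is_count(n_days), n_days >= 1,
            is.numeric(base_rate), base_rate >= 0, base_rate <= 1,
            is.numeric(adherence), adherence > 0, adherence <= 1)
  if (is.null(factors)) {
    factors <- data.frame(name = character(), exposure_prob = numeric(),
                          lag = integer(), effect = numeric())
  }
  stopifnot(is.data.frame(factors),
            all(c("name", "exposure_prob", "lag", "effect") %in% names(factors)))
  if (nrow(factors) > 0) {
    if (any(factors$exposure_prob < 0 | factors$exposure_prob > 1)) {
      stop("factor exposure probabilities must lie in [0, 1]")
    }
    if (!all(factors$lag %in% c(0, 1))) stop("factor lags must be 0 or 1")
    if (anyDuplicated(factors$name)) stop("factor names must be unique")
    if (effect_scale == "risk_difference") {
      each <- base_rate + factors$effect
      if (any(each > 1 + 1e-12 | each < -1e-12)) {
        stop("base_rate plus each applicable risk difference must lie in [0, 1]")
      }
    } else if (any(factors$effect <= 0)) {
      stop("odds ratios must be positive")
    }
  }
  structure(
    list(n_days = as.integer(n_days), base_rate = base_rate,
         factors = factors, adherence = adherence, seed = as.integer(seed),
         effect_scale = effect_scale, start = as.Date(start)),
    class = "nof1_scenario"
  )
}

#' @export
print.nof1_scenario <- function(x, ...) {
  cat(sprintf(
    "Diary simulation scenario: %d days, base rate %.3f, adherence %.2f, seed %d\n",
    x$n_days, x$base_rate, x$adherence, x$seed))
  if (nrow(x$factors) == 0) {
    cat("  no factors\n")
  } else {
    lab <- if (x$effect_scale == "risk_difference") "risk diff" else "odds ratio"
    for (i in seq_len(nrow(x$factors))) {
      f <- x$factors[i, ]
      cat(sprintf("  %s: exposure %.2f, lag %d, %s %+.2f\n",
                  f$name, f$exposure_prob, f$lag, lab, f$effect))
    }
  }
  invisible(x)
}

#' Simulate a diary from a scenario
#'
#' @param scenario An [nof1_scenario()].
#' @param seed Optional seed overriding `scenario$seed` (used by the power
#'   harness to vary replicates).
#' @return An [nof1_diary][diary()] with one outcome column `"outcome"` and
#'   one column per scenario factor, containing only the logged days. The
#'   outcome on day 1 receives no lag-1 contributions (there is no day 0).
#' @export
simulate_diary <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "nof1_scenario"))
  seed <- seed %||% scenario$seed
  n <- scenario$n_days
  fac <- scenario$factors
  with_seed(seed, {
    expo <- matrix(0L, nrow = n, ncol = nrow(fac))
    for (j in seq_len(nrow(fac))) {
      expo[, j] <- stats::rbinom(n, 1, fac$exposure_prob[j])
    }
    if (scenario$effect_scale == "risk_difference") {
      p <- rep(scenario$base_rate, n)
      for (j in seq_len(nrow(fac))) {
        x <- expo[, j]
        if (fac$lag[j] == 1) x <- c(0L, x[-n])
        p <- p + fac$effect[j] * x
      }
      p <- pmin(1, pmax(0, p))
    } else {
      eta <- rep(stats::qlogis(min(max(scenario$base_rate, 1e-12), 1 - 1e-12)), n)
      for (j in seq_len(nrow(fac))) {
        x <- expo[, j]
        if (fac$lag[j] == 1) x <- c(0L, x[-n])
        eta <- eta + log(fac$effect[j]) * x
      }
      p <- stats::plogis(eta)
    }
    outcome <- stats::rbinom(n, 1, p)
    logged <- if (scenario$adherence >= 1) rep(TRUE, n) else
      stats::rbinom(n, 1, scenario$adherence) == 1
    entries <- data.frame(date = scenario$start + (seq_len(n) - 1L),
                          outcome = outcome)
    for (j in seq_len(nrow(fac))) entries[[fac$name[j]]] <- expo[, j]
    entries <- entries[logged, , drop = FALSE]
    diary(entries,
          roles = c(outcome = "outcome",
                    stats::setNames(rep("factor", nrow(fac)), fac$name)),
          subject_id = sprintf("sim-%d", seed))
  })
}

#' @rdname simulate_diary
#' @param object An [nof1_scenario()] (for the [stats::simulate()] generic).
#' @param nsim Number of diaries to simulate.
#' @param ... Unused.
#' @return For `simulate()`: a list of `nsim` diaries, generated under
#'   per-replicate seeds derived from `seed` (or the scenario seed).
#' @export
simulate.nof1_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- derive_seeds(seed %||% object$seed, nsim)
  lapply(seeds, function(s) simulate_diary(object, seed = s))
}

#' Define a detection rule for the power harness
#'
#' A replicate counts as a detection when the screened association for
#' `factor` at `lag` satisfies every requested condition: absolute phi at
#' least `phi_min`, tier at least `min_tier`, and (optionally) top rank in
#' the screen.
#'
#' @param factor Name of the factor whose detection is being scored.
#' @param lag Lag (0 or 1) at which the factor must be flagged.
#' @param phi_min Minimum absolute phi (default 0.3).
#' @param min_tier Minimum tier (`"insufficient"` < `"low"` <
#'   `"moderate"` < `"high"`), or `NULL` for no tier condition. Default
#'   `"moderate"`.
#' @param top_rank Require the association to rank first in the screen
#'   (default `TRUE`).
#' @return An object of class `nof1_detection_rule`.
#' @export
detection_rule <- function(factor, lag = 1, phi_min = 0.3,
                           min_tier = "moderate", top_rank = TRUE) {
  stopifnot(is.character(factor), length(factor) == 1, lag %in% c(0, 1),
            is.numeric(phi_min), phi_min >= 0)
  if (!is.null(min_tier)) {
    min_tier <- match.arg(min_tier,
                          c("insufficient", "low", "moderate", "high"))
  }
  structure(list(factor = factor, lag = as.integer(lag), phi_min = phi_min,
                 min_tier = min_tier, top_rank = isTRUE(top_rank)),
            class = "nof1_detection_rule")
}

apply_detection_rule <- function(screen, rule) {
  hit <- screen$factor == rule$factor & screen$lag == rule$lag
  if (!any(hit)) stop("detection rule references unknown factor/lag: ",
                      rule$factor, " lag ", rule$lag)
  row <- which(hit)[1]
  phi <- screen$phi[row]
  if (is.na(phi) || abs(phi) < rule$phi_min) return(FALSE)
  if (!is.null(rule$min_tier)) {
    levels <- c("insufficient", "low", "moderate", "high")
    if (match(screen$tier[row], levels) < match(rule$min_tier, levels)) {
      return(FALSE)
    }
  }
  if (rule$top_rank && row != 1) return(FALSE)
  TRUE
}

#' Estimate detection power (or type-I error) by simulation
#'
#' Simulates `n_reps` diaries from the scenario, screens each with
#' [nof1_screen()], and reports the fraction of replicates in which the
#' detection rule fires. Under a null scenario (zero effects) with an
#' appropriately calibrated `phi_min` this fraction estimates the type-I
#' error; under an effect scenario it estimates power.
#'
#' @param scenario An [nof1_scenario()].
#' @param n_reps Number of replicates (at least 100).
#' @param rule An [detection_rule()]; defaults to the scenario's first
#'   factor at its stated lag.
#' @param seed Master seed for the replicate stream; defaults to the
#'   scenario seed. Replicate *i* uses a seed derived from it, so results
#'   are reproducible and replicates are independent.
#' @return An object of class `nof1_power` with `detect_rate`,
#'   `mc_se = sqrt(rate (1 - rate) / n_reps)`, `n_reps`, `rule` and
#'   `scenario`.
#' @export
estimate_power <- function(scenario, n_reps = 500, rule = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "nof1_scenario"), is_count(n_reps),
            n_reps >= 100)
  if (is.null(rule)) {
    if (nrow(scenario$factors) == 0) {
      stop("scenario has no factors; supply an explicit detection rule")
    }
    rule <- detection_rule(scenario$factors$name[1],
                           lag = scenario$factors$lag[1])
  }
  stopifnot(inherits(rule, "nof1_detection_rule"))
  if (!rule$factor %in% scenario$factors$name) {
    stop("detection rule references unknown factor: ", rule$factor)
  }
  seeds <- derive_seeds(seed %||% scenario$seed, n_reps)
  hits <- vapply(seeds, function(s) {
    d <- simulate_diary(scenario, seed = s)
    apply_detection_rule(nof1_screen(d), rule)
  }, logical(1))
  rate <- mean(hits)
  structure(list(scenario = scenario, rule = rule,
                 n_reps = as.integer(n_reps), detect_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / n_reps)),
            class = "nof1_power")
}

#' @export
print.nof1_power <- function(x, ...) {
  cat(sprintf(
    "Detection rate %.3f (MC se %.3f) over %d replicates\n  rule: factor '%s' at lag %d, |phi| >= %.2f%s%s\n",
    x$detect_rate, x$mc_se, x$n_reps, x$rule$factor, x$rule$lag,
    x$rule$phi_min,
    if (is.null(x$rule$min_tier)) "" else paste0(", tier >= ", x$rule$min_tier),
    if (x$rule$top_rank) ", top rank" else ""))
  invisible(x)
}

#' Calibrate a phi threshold to a target type-I error
#'
#' Simulates the scenario (which should be a null: the scored factor's
#' effect equal to zero), collects the absolute phi of the scored
#' factor/lag across replicates, and returns the smallest observed |phi|
#' whose empirical exceedance probability does not exceed `alpha`. Because
#' phi takes discrete values on finite tables, the achieved level is
#' reported alongside the threshold and is the honest comparison point for
#' subsequent type-I-error checks.
#'
#' @param scenario A null [nof1_scenario()].
#' @param factor,lag The association to calibrate on.
#' @param alpha Target type-I error.
#' @param n_reps Calibration replicates.
#' @param seed Master seed (defaults to the scenario seed).
#' @return List with `threshold`, `alpha_achieved`, `alpha`, `n_reps`.
#' @export
calibrate_phi_threshold <- function(scenario, factor = NULL, lag = 1,
                                    alpha = 0.1, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(scenario, "nof1_scenario"), alpha > 0, alpha < 1,
            is_count(n_reps), n_reps >= 100)
  factor <- factor %||% scenario$factors$name[1]
  seeds <- derive_seeds(seed %||% scenario$seed, n_reps)
  abs_phi <- vapply(seeds, function(s) {
    d <- simulate_diary(scenario, seed = s)
    tab <- build_contingency(d, "outcome", factor, lag)
    phi <- phi_coef(tab)
    if (is.na(phi)) 0 else abs(phi)
  }, numeric(1))
  cand <- sort(unique(abs_phi))
  exceed <- vapply(cand, function(t) mean(abs_phi >= t), numeric(1))
  ok <- which(exceed <= alpha)
  if (length(ok) == 0) {
    threshold <- max(abs_phi) + .Machine$double.eps
    achieved <- 0
  } else {
    threshold <- cand[ok[1]]
    achieved <- exceed[ok[1]]
  }
  list(threshold = threshold, alpha_achieved = achieved, alpha = alpha,
       n_reps = as.integer(n_reps))
}
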