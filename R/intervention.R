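#' Compare outcome recurrence between baseline and intervention phases
#'
#' The hypothesis-testing step of the N-of-1 cycle: after the user adopts a
#' lifestyle modification, did the daily recurrence rate of the outcome
#' change? The unit of analysis is the logged day (outcome observed 0/1);
#' unlogged days and days with a missing outcome value are excluded from
#' both numerator and denominator rather than imputed. The two-sided
#' p-value comes from [fisher_exact_2x2()] on the phase-by-outcome-day
#' table.
#'
#' @param diary A two-phase [nof1_diary][diary()] object.
#' @param outcome Name of the outcome variable; defaults to the diary's
#'   first (or only) outcome.
#' @return An object of class `nof1_phase_comparison` with components
#'   `outcome`, `baseline_days`, `baseline_events`, `intervention_days`,
#'   `intervention_events`, `baseline_rate`, `intervention_rate`,
#'   `rate_difference` (intervention minus baseline) and `p_two_sided`.
#' @export
compare_phases <- function(diary, outcome = NULL) {
  stopifnot(inherits(diary, "nof1_diary"))
  outcomes <- diary_variables(diary, "outcome")
  outcome <- outcome %||% outcomes[1]
  if (!outcome %in% outcomes) {
    stop("'", outcome, "' is not an outcome variable of this diary")
  }
  phase_counts <- lapply(c("baseline", "intervention"), function(lab) {
    o <- slice_phase(diary, lab)$entries[[outcome]]
    o <- o[!is.na(o)]
    if (length(o) == 0) {
      stop(sprintf("phase has no data: no logged '%s' days in the %s phase",
                   outcome, lab))
    }
    c(days = length(o), events = sum(o))
  })
  b <- phase_counts[[1]]
  i <- phase_counts[[2]]
  tab <- matrix(c(b[["events"]], b[["days"]] - b[["events"]],
                  i[["events"]], i[["days"]] - i[["events"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(phase = c("baseline", "intervention"),
                                outcome = c("event", "no event")))
  structure(
    list(outcome = outcome,
         baseline_days = b[["days"]], baseline_events = b[["events"]],
         intervention_days = i[["days"]], intervention_events = i[["events"]],
         baseline_rate = b[["events"]] / b[["days"]],
         intervention_rate = i[["events"]] / i[["days"]],
         rate_difference = i[["events"]] / i[["days"]] - b[["events"]] / b[["days"]],
         p_two_sided = fisher_exact_2x2(tab),
         table = tab),
    class = "nof1_phase_comparison"
  )
}

#' @export
print.nof1_phase_comparison <- function(x, ...) {
  cat(sprintf("Phase comparison for outcome '%s'\n", x$outcome))
  cat(sprintf("  baseline:     %d events / %d logged days (rate %.3f)\n",
              x$baseline_events, x$baseline_days, x$baseline_rate))
  cat(sprintf("  intervention: %d events / %d logged days (rate %.3f)\n",
              x$intervention_events, x$intervention_days, x$intervention_rate))
  cat(sprintf("  rate difference: %+.3f events/day\n", x$rate_difference))
  cat(sprintf("  two-sided exact p = %.4g\n", x$p_two_sided))
  invisible(x)
}

#' Summarise a full N-of-1 cycle
#'
#' One artifact for the complete hypothesis-generation / hypothesis-testing
#' loop: the phi screen ([nof1_screen()]) run on the baseline phase, and —
#' when the diary has an intervention phase — a [compare_phases()] result
#' for each outcome with logged days in both phases.
#'
#' @param diary An [nof1_diary][diary()] object.
#' @param ... Passed on to [nof1_screen()].
#' @return An object of class `nof1_cycle` with components `screen` and
#'   `comparisons` (a possibly empty named list of
#'   `nof1_phase_comparison`).
#' @export
nof1_cycle <- function(diary, ...) {
  stopifnot(inherits(diary, "nof1_diary"))
  screen <- nof1_screen(slice_phase(diary, "baseline"), ...)
  comparisons <- list()
  if (any(diary$entries$phase == "intervention")) {
    for (out in diary_variables(diary, "outcome")) {
      cmp <- tryCatch(compare_phases(diary, out), error = function(e) NULL)
      if (!is.null(cmp)) comparisons[[out]] <- cmp
    }
  }
  structure(list(subject_id = diary$subject_id, screen = screen,
                 comparisons = comparisons),
            class = "nof1_cycle")
}

#' @export
print.nof1_cycle <- function(x, ...) {
  cat(sprintf("N-of-1 cycle report for subject '%s'\n", x$subject_id))
  cat("\n-- Hypothesis generation (baseline phase) --\n")
  print(x$screen)
  if (length(x$comparisons) > 0) {
    cat("\n-- Hypothesis testing (baseline vs intervention) --\n")
    for (cmp in x$comparisons) print(cmp)
  } else {
    cat("\n(no intervention phase: hypothesis testing not yet available)\n")
  }
  invisible(x)
}

#' @export
as.list.nof1_cycle <- function(x, ...) {
  out <- list(subject_id = x$subject_id,
              associations = as.data.frame(x$screen))
  if (length(x$comparisons) > 0) {
    out$comparisons <- lapply(x$comparisons, function(cmp) {
      cmp$table <- NULL
      unclass(cmp)
    })
  }
  out
}
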