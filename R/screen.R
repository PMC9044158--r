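#' Default confidence-tier thresholds for phi screening
#'
#' Correlation estimates from a handful of diary days are unstable; the
#' screen therefore labels each association by the number of complete day
#' pairs supporting it. With fewer than `insufficient` pairs no phi is
#' reported at all; above that, tiers are a qualitative reliability label,
#' not a significance statement.
#'
#' @param insufficient Minimum number of pairs before any phi is reported
#'   (default 3: screening starts after three days of data).
#' @param moderate,high Lower pair counts for the `"moderate"` and
#'   `"high"` tiers; pairs between `insufficient` and `moderate - 1` are
#'   `"low"`.
#' @return Named integer vector used by [nof1_screen()].
#' @export
tier_thresholds <- function(insufficient = 3, moderate = 14, high = 30) {
  stopifnot(is_count(insufficient), is_count(moderate), is_count(high),
            insufficient <= moderate, moderate <= high)
  c(insufficient = as.integer(insufficient), moderate = as.integer(moderate),
    high = as.integer(high))
}

assign_tier <- function(n_days, thresholds) {
  cut(n_days,
      breaks = c(-Inf, thresholds[["insufficient"]] - 0.5,
                 thresholds[["moderate"]] - 0.5, thresholds[["high"]] - 0.5, Inf),
      labels = c("insufficient", "low", "moderate", "high"))
}

#' Screen all factor-outcome pairs of a diary for phi associations
#'
#' The hypothesis-generation step of the N-of-1 cycle: every factor is
#' cross-tabulated against every outcome at lag 0 (same day) and lag 1
#' (factor on the previous day), the phi coefficient is computed for each
#' table, and the results are ranked by absolute phi. Associations with
#' fewer complete day pairs than the `insufficient` threshold (default 3)
#' are reported with tier `"insufficient"` and no phi value; associations
#' whose table has a zero marginal (a constant column) are reported as
#' undefined with the reason. Undefined results sort after all defined
#' ones.
#'
#' No multiplicity adjustment is applied by default — the screen surfaces
#' raw correlations as candidate hypotheses for the user to test by
#' intervention, not confirmatory findings. For research use,
#' `adjust = "bonferroni"` adds exact-test p-values
#' ([fisher_exact_2x2()]) with a Bonferroni correction across factors
#' within each outcome and lag.
#'
#' @param diary An [nof1_diary][diary()] object.
#' @param lags Integer subset of `c(0, 1)`.
#' @param thresholds Tier thresholds from [tier_thresholds()].
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return An object of class `nof1_screen`: a data frame with one row per
#'   (outcome, factor, lag), columns `outcome`, `factor`, `lag`, `phi`,
#'   `n_days`, `n11`, `n10`, `n01`, `n00`, `tier`, `reason` (and `p`,
#'   `p_adj` when adjusted), ranked by `|phi|` descending with ties broken
#'   by larger `n_days` then factor name.
#' @examples
#' d <- diary(data.frame(date = as.Date("2024-01-01") + 0:9,
#'                       flare = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0),
#'                       coffee = c(1, 0, 1, 1, 0, 0, 1, 0, 0, 1),
#'                       stress = c(0, 0, 1, 0, 1, 0, 0, 1, 0, 1)),
#'            roles = c(flare = "outcome", coffee = "factor",
#'                      stress = "factor"))
#' nof1_screen(d)
#' @export
nof1_screen <- function(diary, lags = c(0, 1), thresholds = tier_thresholds(),
                        adjust = c("none", "bonferroni")) {
  stopifnot(inherits(diary, "nof1_diary"))
  adjust <- match.arg(adjust)
  if (length(lags) == 0 || !all(lags %in% c(0, 1))) stop("lags must be within {0, 1}")
  outcomes <- diary_variables(diary, "outcome")
  factors <- diary_variables(diary, "factor")

  grid <- expand.grid(factor = factors, outcome = outcomes, lag = sort(lags),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tab <- build_contingency(diary, g$outcome, g$factor, g$lag)
    phi <- phi_coef(tab)
    reason <- attr(phi, "reason") %||% NA_character_
    if (tab$total < thresholds[["insufficient"]]) {
      phi <- NA_real_
      reason <- sprintf("insufficient data (<%d pairs)",
                        thresholds[["insufficient"]])
    }
    data.frame(outcome = g$outcome, factor = g$factor, lag = as.integer(g$lag),
               phi = as.numeric(phi), n_days = tab$total,
               n11 = tab$n11, n10 = tab$n10, n01 = tab$n01, n00 = tab$n00,
               tier = as.character(assign_tier(tab$total, thresholds)),
               reason = reason, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows) %||%
    data.frame(outcome = character(), factor = character(), lag = integer(),
               phi = numeric(), n_days = integer(), n11 = integer(),
               n10 = integer(), n01 = integer(), n00 = integer(),
               tier = character(), reason = character())

  if (adjust == "bonferroni" && nrow(res) > 0) {
    res$p <- vapply(seq_len(nrow(res)), function(i) {
      fisher_exact_2x2(contingency_2x2(res$n11[i], res$n10[i],
                                       res$n01[i], res$n00[i]))
    }, numeric(1))
    res$p_adj <- NA_real_
    for (key in split(seq_len(nrow(res)),
                      interaction(res$outcome, res$lag, drop = TRUE))) {
      res$p_adj[key] <- stats::p.adjust(res$p[key], method = "bonferroni")
    }
  }

  defined <- !is.na(res$phi)
  ord_def <- order(-abs(res$phi[defined]), -res$n_days[defined],
                   res$factor[defined], res$lag[defined])
  ord_und <- order(-res$n_days[!defined], res$factor[!defined],
                   res$lag[!defined])
  res <- rbind(res[defined, , drop = FALSE][ord_def, , drop = FALSE],
               res[!defined, , drop = FALSE][ord_und, , drop = FALSE])
  rownames(res) <- NULL
  structure(res, class = c("nof1_screen", "data.frame"),
            thresholds = thresholds, subject_id = diary$subject_id)
}

#' @export
print.nof1_screen <- function(x, digits = 4, ...) {
  cat(sprintf("Phi association screen for subject '%s' (%d pairing%s)\n",
              attr(x, "subject_id"), nrow(x), if (nrow(x) == 1) "" else "s"))
  if (nrow(x) == 0) {
    cat("  (no factor variables to screen)\n")
    return(invisible(x))
  }
  show <- as.data.frame(x)
  show$phi <- ifelse(is.na(show$phi), NA, sprintf("%.*f", digits, show$phi))
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nof1_screen <- function(object, ...) {
  top <- object[!is.na(object$phi), , drop = FALSE]
  cat(sprintf("%d associations screened; %d with defined phi\n",
              nrow(object), nrow(top)))
  if (nrow(top) > 0) {
    lead <- top[1, ]
    cat(sprintf("Leading candidate: %s -> %s at lag %d (phi = %.4f, %d pairs, tier %s)\n",
                lead$factor, lead$outcome, lead$lag, lead$phi, lead$n_days,
                lead$tier))
  }
  invisible(object)
}

#' Serialise a screening report
#'
#' @param x An `nof1_screen` object.
#' @param format `"tsv"` or `"json"`.
#' @return A character vector (TSV lines) or a JSON string, with phi
#'   formatted to 4 decimal places.
#' @export
format_screen <- function(x, format = c("tsv", "json")) {
  stopifnot(inherits(x, "nof1_screen"))
  format <- match.arg(format)
  df <- as.data.frame(x)
  df$phi <- ifelse(is.na(df$phi), NA, as.numeric(sprintf("%.4f", df$phi)))
  if (format == "json") {
    return(jsonlite::toJSON(df, dataframe = "rows", na = "null", pretty = TRUE))
  }
  df$phi <- ifelse(is.na(df$phi), NA, sprintf("%.4f", df$phi))
  header <- paste(names(df), collapse = "\t")
  body <- apply(df, 1, function(r) paste(ifelse(is.na(r), "", trimws(r)),
                                         collapse = "\t"))
  unname(c(header, if (nrow(df) > 0) body))
}
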