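#' 2x2 contingency table of factor presence by outcome presence
#'
#' @param n11 Days with factor present and outcome present.
#' @param n10 Days with factor present and outcome absent.
#' @param n01 Days with factor absent and outcome present.
#' @param n00 Days with factor absent and outcome absent.
#' @return An object of class `nof1_table2x2` with the four counts and the
#'   total.
#' @export
contingency_2x2 <- function(n11, n10, n01, n00) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (!all(vapply(counts, is_count, logical(1)))) {
    stop("contingency counts must be single nonnegative integers")
  }
  structure(
    list(n11 = as.integer(n11), n10 = as.integer(n10),
         n01 = as.integer(n01), n00 = as.integer(n00),
         total = as.integer(n11 + n10 + n01 + n00)),
    class = "nof1_table2x2"
  )
}

#' @export
print.nof1_table2x2 <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), nrow = 2, byrow = TRUE,
              dimnames = list(factor = c("present", "absent"),
                              outcome = c("present", "absent")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.nof1_table2x2 <- function(x, ...) {
  matrix(c(x$n11, x$n10, x$n01, x$n00), nrow = 2, byrow = TRUE,
         dimnames = list(factor = c("present", "absent"),
                         outcome = c("present", "absent")))
}

#' Cross-tabulate a factor against an outcome at lag 0 or lag 1
#'
#' Lag 0 pairs each day's factor value with the same day's outcome. Lag 1
#' pairs day *t*'s factor with day *t+1*'s outcome, and only when the two
#' dates are consecutive calendar days — a gap in logging breaks the pair,
#' because an unlogged day carries no information. Pairs in which either
#' value is missing are dropped (pairwise-complete analysis).
#'
#' @param diary An [nof1_diary][diary()] object.
#' @param outcome Name of a variable with role `"outcome"`.
#' @param factor Name of a variable with role `"factor"`.
#' @param lag 0 (same-day association) or 1 (factor on the day before the
#'   outcome). Longer lags are rejected.
#' @return An `nof1_table2x2` of the complete (factor, outcome) day pairs.
#' @examples
#' d <- diary(data.frame(date = as.Date("2024-01-01") + 0:3,
#'                       o = c(1, 0, 1, 0), f = c(1, 1, 0, 0)),
#'            roles = c(o = "outcome", f = "factor"))
#' build_contingency(d, "o", "f", lag = 0)
#' build_contingency(d, "o", "f", lag = 1)
#' @export
build_contingency <- function(diary, outcome, factor, lag = 0) {
  stopifnot(inherits(diary, "nof1_diary"))
  if (!outcome %in% diary_variables(diary, "outcome")) {
    stop("'", outcome, "' is not an outcome variable of this diary")
  }
  if (!factor %in% diary_variables(diary, "factor")) {
    stop("'", factor, "' is not a factor variable of this diary")
  }
  if (!is_count(lag) || !lag %in% c(0, 1)) {
    stop("lag must be 0 or 1")
  }
  e <- diary$entries
  f <- e[[factor]]
  o <- e[[outcome]]
  if (lag == 0) {
    keep <- !is.na(f) & !is.na(o)
    fp <- f[keep]
    op <- o[keep]
  } else if (nrow(e) >= 2) {
    i <- seq_len(nrow(e) - 1L)
    consecutive <- as.numeric(e$date[i + 1L] - e$date[i]) == 1
    keep <- consecutive & !is.na(f[i]) & !is.na(o[i + 1L])
    fp <- f[i][keep]
    op <- o[i + 1L][keep]
  } else {
    fp <- integer(0)
    op <- integer(0)
  }
  contingency_2x2(sum(fp == 1 & op == 1), sum(fp == 1 & op == 0),
                  sum(fp == 0 & op == 1), sum(fp == 0 & op == 0))
}

#' Phi coefficient of a 2x2 table
#'
#' The phi coefficient is the Pearson product-moment correlation of two
#' binary variables, computed from their 2x2 cross-tabulation as
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) / \sqrt{r_1 r_0 c_1 c_0}}
#' with \eqn{r}, \eqn{c} the row and column totals. When any marginal is
#' zero (one of the variables never varies) phi is undefined; this returns
#' `NA` with a machine-readable `reason` attribute rather than an error,
#' since constant columns are routine in short diaries.
#'
#' @param table An `nof1_table2x2` from [contingency_2x2()] or
#'   [build_contingency()].
#' @return Phi in \[-1, 1\], or `NA_real_` with attribute `reason` in
#'   `"no pairs"`, `"no variation in factor"`, `"no variation in outcome"`.
#' @examples
#' phi_coef(contingency_2x2(5, 0, 0, 5)) # 1
#' phi_coef(contingency_2x2(2, 2, 2, 2)) # 0
#' @export
phi_coef <- function(table) {
  stopifnot(inherits(table, "nof1_table2x2"))
  n11 <- as.numeric(table$n11); n10 <- as.numeric(table$n10)
  n01 <- as.numeric(table$n01); n00 <- as.numeric(table$n00)
  r1 <- n11 + n10; r0 <- n01 + n00
  c1 <- n11 + n01; c0 <- n10 + n00
  if (table$total == 0) {
    return(structure(NA_real_, reason = "no pairs"))
  }
  if (r1 == 0 || r0 == 0) {
    return(structure(NA_real_, reason = "no variation in factor"))
  }
  if (c1 == 0 || c0 == 0) {
    return(structure(NA_real_, reason = "no variation in outcome"))
  }
  (n11 * n00 - n10 * n01) / sqrt(r1 * r0 * c1 * c0)
}
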