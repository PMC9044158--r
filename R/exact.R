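# Exact tests of proportions. Two-sided p-values use the probability-
# ordering rule: sum the null probabilities of every table with the observed
# margins whose probability does not exceed the observed table's (within a
# small relative tolerance so that ties are counted reproducibly regardless
# of arithmetic order).

PROB_TIE_TOL <- 1e-7

#' Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution; the two-sided p-value sums the probabilities of all tables
#' as or less probable than the one observed (probability-ordering rule,
#' relative tie tolerance 1e-7). A table with a zero margin admits only one
#' configuration, so the p-value is 1.
#'
#' @param table An `nof1_table2x2` ([contingency_2x2()]) or a 2x2 numeric
#'   matrix of counts.
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' fisher_exact_2x2(contingency_2x2(3, 1, 1, 3)) # 34/70
#' @export
fisher_exact_2x2 <- function(table) {
  if (inherits(table, "nof1_table2x2")) table <- as.matrix(table)
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0),
            all(table == floor(table)))
  r1 <- sum(table[1, ]); r0 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c0 <- sum(table[, 2])
  if (r1 == 0 || r0 == 0 || c1 == 0 || c0 == 0) return(1)
  support <- max(0, c1 - r0):min(r1, c1)
  probs <- stats::dhyper(support, c1, c0, r1)
  p_obs <- probs[support == table[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + PROB_TIE_TOL)]))
}

# log null probability of an RxC table with the given margins:
# P(T) = prod(r_i!) prod(c_j!) / (N! prod(n_ij!))
log_table_prob_const <- function(rows, cols) {
  sum(lgamma(rows + 1)) + sum(lgamma(cols + 1)) - lgamma(sum(rows) + 1)
}

# Count the number of nonnegative integer tables with the given margins,
# by dynamic programming over rows (memoised on the remaining column
# margins). Used to decide between full enumeration and Monte Carlo.
count_margin_tables <- function(rows, cols) {
  memo <- new.env(parent = emptyenv())
  compositions <- function(total, caps) {
    # all ways to split `total` across cells bounded by caps
    if (length(caps) == 1L) {
      if (total <= caps) return(list(total)) else return(list())
    }
    out <- list()
    for (k in 0:min(total, caps[1])) {
      rest <- compositions(total - k, caps[-1])
      out <- c(out, lapply(rest, function(r) c(k, r)))
    }
    out
  }
  count <- function(i, rem) {
    if (i > length(rows)) return(if (all(rem == 0)) 1 else 0)
    key <- paste(i, paste(rem, collapse = ","))
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- 0
    for (comp in compositions(rows[i], rem)) {
      total <- total + count(i + 1L, rem - comp)
    }
    memo[[key]] <- total
    total
  }
  count(1L, cols)
}

# Exact two-sided p by full enumeration of all tables with the observed
# margins, probability-ordering rule. Recursion over rows; the last row is
# forced by the column margins.
enumerate_rxc_p <- function(counts) {
  rows <- rowSums(counts)
  cols <- colSums(counts)
  const <- log_table_prob_const(rows, cols)
  lp_obs <- const - sum(lgamma(counts + 1))
  cutoff <- lp_obs + log1p(PROB_TIE_TOL)
  R <- length(rows)
  total_p <- 0
  recurse <- function(i, rem, lgacc) {
    if (i == R) {
      # rem is exactly the forced last row
      lp <- const - lgacc - sum(lgamma(rem + 1))
      if (lp <= cutoff) total_p <<- total_p + exp(lp)
      return(invisible())
    }
    fill_row <- function(j, left, rem_j, lg) {
      if (j == length(cols)) {
        if (left <= rem_j[j]) {
          rem2 <- rem_j
          rem2[j] <- rem2[j] - left
          # prune: remaining rows must be able to absorb rem2
          if (sum(rem2) == sum(rows[(i + 1):R])) {
            recurse(i + 1L, rem2, lg + lgamma(left + 1))
          }
        }
        return(invisible())
      }
      for (k in 0:min(left, rem_j[j])) {
        rem2 <- rem_j
        rem2[j] <- rem2[j] - k
        fill_row(j + 1L, left - k, rem2, lg + lgamma(k + 1))
      }
    }
    fill_row(1L, rows[i], rem, lgacc)
  }
  recurse(1L, cols, 0)
  min(1, total_p)
}

#' Fisher-type exact test for an RxC table
#'
#' Generalises [fisher_exact_2x2()] to R x C tables of counts, testing
#' homogeneity of the column distribution across rows conditional on both
#' margins. When the lattice of tables sharing the observed margins is
#' small enough it is enumerated in full; otherwise the p-value is
#' estimated by Monte Carlo over margin-preserving tables drawn with
#' [stats::r2dtable()], using the add-one estimator
#' (1 + #\{as extreme\}) / (reps + 1).
#'
#' @param counts Numeric matrix of nonnegative integer counts, at least
#'   2 x 2, with at least one positive entry.
#' @param max_enumeration Largest table-lattice size enumerated exactly.
#' @param mc_reps Monte Carlo replicates when enumeration is infeasible
#'   (must be at least 1000).
#' @param seed RNG seed for the Monte Carlo path; the caller's RNG state is
#'   left untouched.
#' @return A list of class `nof1_exact` with `p` (two-sided p-value),
#'   `method` (`"enumeration"` or `"monte_carlo"`), `n_tables` (lattice
#'   size), and for the Monte Carlo path `mc_reps` and `mc_se`.
#' @examples
#' fisher_exact_rxc(matrix(c(5, 0, 0, 0, 5, 0), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_rxc <- function(counts, max_enumeration = 1e5, mc_reps = 1e5,
                             seed = 1L) {
  stopifnot(is.matrix(counts), nrow(counts) >= 2, ncol(counts) >= 2,
            all(counts >= 0), all(counts == floor(counts)), sum(counts) > 0)
  counts <- matrix(as.integer(counts), nrow(counts))
  rows <- rowSums(counts)
  cols <- colSums(counts)
  # rows or columns with zero margin admit a single configuration (all
  # zero) and do not affect the ordering of table probabilities
  counts <- counts[rows > 0, cols > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    return(structure(list(p = 1, method = "enumeration", n_tables = 1L),
                     class = "nof1_exact"))
  }
  rows <- rowSums(counts)
  cols <- colSums(counts)

  n_tables <- count_margin_tables(rows, cols)
  if (n_tables <= max_enumeration) {
    p <- enumerate_rxc_p(counts)
    return(structure(list(p = p, method = "enumeration",
                          n_tables = n_tables), class = "nof1_exact"))
  }
  if (mc_reps < 1000) {
    stop("mc_reps must be at least 1000 when Monte Carlo sampling is required")
  }
  const <- log_table_prob_const(rows, cols)
  lp_obs <- const - sum(lgamma(counts + 1))
  cutoff <- lp_obs + log1p(PROB_TIE_TOL)
  hits <- with_seed(seed, {
    tabs <- stats::r2dtable(mc_reps, rows, cols)
    sum(vapply(tabs, function(t) (const - sum(lgamma(t + 1))) <= cutoff,
               logical(1)))
  })
  p <- (1 + hits) / (mc_reps + 1)
  structure(list(p = p, method = "monte_carlo", n_tables = n_tables,
                 mc_reps = as.integer(mc_reps),
                 mc_se = sqrt(p * (1 - p) / mc_reps)),
            class = "nof1_exact")
}

#' @export
print.nof1_exact <- function(x, ...) {
  cat(sprintf("Exact test of homogeneity: p = %.4g (%s", x$p, x$method))
  if (x$method == "monte_carlo") {
    cat(sprintf(", %d reps, MC se %.2g", x$mc_reps, x$mc_se))
  } else {
    cat(sprintf(", %s tables", format(x$n_tables, big.mark = ",")))
  }
  cat(")\n")
  invisible(x)
}
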