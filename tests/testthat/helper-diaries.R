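# Shared generators for property-style tests. All randomness is drawn
# inside withr-free local seeds via nof1diary's own simulator or plain
# set.seed in the calling test.

# A random valid diary: 1-2 outcomes, 0-3 factors, optional missing values,
# calendar gaps, and an optional intervention tail.
random_diary <- function(n_days = sample(0:40, 1)) {
  n_out <- sample(1:2, 1)
  n_fac <- sample(0:3, 1)
  vars <- c(paste0("out", seq_len(n_out)),
            if (n_fac > 0) paste0("fac", seq_len(n_fac)))
  roles <- stats::setNames(rep(c("outcome", "factor"), c(n_out, n_fac)), vars)
  # strictly increasing dates with random gaps
  dates <- as.Date("2023-06-01") + cumsum(sample(1:3, n_days, replace = TRUE))
  entries <- data.frame(date = dates)
  for (v in vars) {
    x <- sample(c(0L, 1L, NA), n_days, replace = TRUE,
                prob = c(0.45, 0.45, 0.1))
    entries[[v]] <- x
  }
  if (n_days > 4 && runif(1) < 0.5) {
    cut <- sample(seq(2, n_days - 1), 1)
    entries$phase <- rep(c("baseline", "intervention"),
                         c(cut, n_days - cut))
  }
  diary(entries, roles = roles,
        subject_id = paste0("subj-", sample(1e6, 1)))
}

# A random 2x2 table with all four marginals positive.
random_positive_margin_table <- function(max_cell = 12) {
  repeat {
    n <- sample(0:max_cell, 4, replace = TRUE)
    tab <- contingency_2x2(n[1], n[2], n[3], n[4])
    if ((tab$n11 + tab$n10) > 0 && (tab$n01 + tab$n00) > 0 &&
        (tab$n11 + tab$n01) > 0 && (tab$n10 + tab$n00) > 0) {
      return(tab)
    }
  }
}

# Pearson correlation of the expanded 0/1 vectors of a 2x2 table: the
# independent oracle for phi.
phi_pearson_oracle <- function(tab) {
  f <- rep(c(1, 1, 0, 0), c(tab$n11, tab$n10, tab$n01, tab$n00))
  o <- rep(c(1, 0, 1, 0), c(tab$n11, tab$n10, tab$n01, tab$n00))
  suppressWarnings(stats::cor(f, o))
}
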