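#' Construct an N-of-1 diary
#'
#' A diary is a single subject's date-ordered record of binary daily
#' observations: one or more outcomes (e.g. "did a migraine occur today?")
#' and zero or more candidate risk factors (e.g. "did I drink coffee
#' today?"). Each logged day belongs to a study phase, either `"baseline"`
#' or `"intervention"`; days are `"baseline"` unless stated otherwise, so a
#' single-phase diary needs no phase information at all.
#'
#' Calendar gaps are allowed and meaningful: an unlogged day carries no
#' information, which is distinct from a logged day with value 0 (the event
#' or exposure did not occur). Lag-1 pairing in [build_contingency()] relies
#' on this distinction, pairing only consecutive calendar days.
#'
#' @param entries A data frame with a `date` column (`Date` or parseable
#'   `"YYYY-MM-DD"` strings), an optional `phase` column
#'   (`"baseline"`/`"intervention"`, blank or `NA` meaning baseline), and one
#'   column per variable holding values 0, 1 or `NA` (missing).
#' @param roles Named character vector mapping each variable column to its
#'   role, `"outcome"` or `"factor"`. At least one variable must be an
#'   outcome. If unnamed, names are taken from the variable columns in
#'   order. If `NULL`, the first variable column is the outcome and the rest
#'   are factors.
#' @param subject_id Opaque subject identifier string.
#' @return An object of class `nof1_diary`: a list with components
#'   `subject_id`, `variables` (data frame of `name`, `role`) and `entries`
#'   (data frame of `date`, `phase` and one 0/1/`NA` integer column per
#'   variable, sorted by date).
#' @examples
#' d <- diary(
#'   data.frame(
#'     date = as.Date("2024-03-01") + 0:4,
#'     migraine = c(1, 0, 1, 0, 0),
#'     caffeine = c(1, 1, 0, NA, 0)
#'   ),
#'   roles = c(migraine = "outcome", caffeine = "factor")
#' )
#' d
#' @seealso [read_diary()], [write_diary()], [slice_phase()]
#' @export
diary <- function(entries, roles = NULL, subject_id = "subject") {
  stopifnot(is.data.frame(entries))
  if (!"date" %in% names(entries)) stop("entries must have a 'date' column")
  date <- entries[["date"]]
  if (!inherits(date, "Date")) date <- as.Date(as.character(date))
  if (anyNA(date)) stop("entries contain unparseable dates")

  phase <- if ("phase" %in% names(entries)) as.character(entries[["phase"]]) else
    rep("baseline", nrow(entries))
  phase[is.na(phase) | phase == ""] <- "baseline"
  bad <- setdiff(unique(phase), c("baseline", "intervention"))
  if (length(bad) > 0) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  }

  var_names <- setdiff(names(entries), c("date", "phase"))
  if (length(var_names) == 0) stop("diary has no variable columns")

  if (is.null(roles)) {
    roles <- c("outcome", rep("factor", length(var_names) - 1L))
    names(roles) <- var_names
  }
  if (is.null(names(roles))) names(roles) <- var_names
  if (!setequal(names(roles), var_names)) {
    stop("roles must name exactly the variable columns: ",
         paste(var_names, collapse = ", "))
  }
  roles <- roles[var_names]
  if (!all(roles %in% c("outcome", "factor"))) {
    stop("roles must be 'outcome' or 'factor'")
  }
  if (!any(roles == "outcome")) stop("at least one variable must be an outcome")

  vals <- lapply(var_names, function(v) {
    x <- entries[[v]]
    if (is.character(x)) x[x == ""] <- NA
    x <- suppressWarnings(as.integer(as.character(x)))
    x
  })
  names(vals) <- var_names
  for (v in var_names) {
    x <- vals[[v]]
    raw <- entries[[v]]
    bad_idx <- which((!is.na(raw) & as.character(raw) != "" & is.na(x)) |
                       (!is.na(x) & !(x %in% c(0L, 1L))))
    if (length(bad_idx) > 0) {
      stop(sprintf("invalid value for '%s' on %s: values must be 0, 1 or blank",
                   v, format(date[bad_idx[1]])))
    }
  }

  ord <- order(date)
  date <- date[ord]
  phase <- phase[ord]
  if (anyDuplicated(date)) {
    stop("duplicate diary date: ", format(date[which(duplicated(date))[1]]))
  }

  out <- data.frame(date = date, phase = phase, stringsAsFactors = FALSE)
  for (v in var_names) out[[v]] <- vals[[v]][ord]
  rownames(out) <- NULL

  structure(
    list(
      subject_id = as.character(subject_id),
      variables = data.frame(name = var_names, role = unname(roles),
                             stringsAsFactors = FALSE),
      entries = out
    ),
    class = "nof1_diary"
  )
}

#' @export
print.nof1_diary <- function(x, ...) {
  n <- nrow(x$entries)
  cat(sprintf("N-of-1 diary for subject '%s': %d logged day%s\n",
              x$subject_id, n, if (n == 1) "" else "s"))
  if (n > 0) {
    cat(sprintf("  span: %s to %s\n", format(min(x$entries$date)),
                format(max(x$entries$date))))
  }
  for (role in c("outcome", "factor")) {
    v <- x$variables$name[x$variables$role == role]
    if (length(v)) cat(sprintf("  %ss: %s\n", role, paste(v, collapse = ", ")))
  }
  tab <- table(factor(x$entries$phase, levels = c("baseline", "intervention")))
  cat(sprintf("  phases: baseline %d day(s), intervention %d day(s)\n",
              tab[["baseline"]], tab[["intervention"]]))
  invisible(x)
}

#' @export
summary.nof1_diary <- function(object, ...) {
  e <- object$entries
  vars <- object$variables$name
  stats <- data.frame(
    variable = vars,
    role = object$variables$role,
    days_logged = vapply(vars, function(v) sum(!is.na(e[[v]])), integer(1)),
    days_present = vapply(vars, function(v) sum(e[[v]] == 1, na.rm = TRUE),
                          integer(1)),
    stringsAsFactors = FALSE
  )
  stats$rate <- ifelse(stats$days_logged > 0,
                       stats$days_present / stats$days_logged, NA_real_)
  rownames(stats) <- NULL
  structure(list(subject_id = object$subject_id, n_days = nrow(e),
                 variables = stats), class = "summary.nof1_diary")
}

#' @export
print.summary.nof1_diary <- function(x, ...) {
  cat(sprintf("Diary '%s': %d logged days\n", x$subject_id, x$n_days))
  print(x$variables, row.names = FALSE)
  invisible(x)
}

#' Names of diary variables with a given role
#' @param diary An [nof1_diary][diary()] object.
#' @param role `"outcome"` or `"factor"`.
#' @return Character vector of variable names.
#' @export
diary_variables <- function(diary, role = c("outcome", "factor")) {
  stopifnot(inherits(diary, "nof1_diary"))
  role <- match.arg(role)
  diary$variables$name[diary$variables$role == role]
}

#' Phase spans of a diary
#'
#' Summarises the per-day phase labels as contiguous spans (label, first
#' date, last date), in date order.
#'
#' @param diary An [nof1_diary][diary()] object.
#' @return Data frame with columns `label`, `start`, `end`, `n_days`.
#' @export
phase_spans <- function(diary) {
  stopifnot(inherits(diary, "nof1_diary"))
  e <- diary$entries
  if (nrow(e) == 0) {
    return(data.frame(label = character(), start = as.Date(character()),
                      end = as.Date(character()), n_days = integer()))
  }
  run <- cumsum(c(TRUE, e$phase[-1] != e$phase[-nrow(e)]))
  out <- do.call(rbind, lapply(split(seq_len(nrow(e)), run), function(i) {
    data.frame(label = e$phase[i[1]], start = e$date[i[1]],
               end = e$date[i[length(i)]], n_days = length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a diary from CSV
#'
#' Expected layout: a header line `date,phase,<var1>,<var2>,...` (the
#' `phase` column is optional), optionally followed by comment lines
#' starting with `#` before the data rows:
#' * `#role,...` — one field per header column; variable columns carry
#'   `outcome` or `factor`, other columns are left blank.
#' * `#subject,<id>` — the subject identifier (a format extension; defaults
#'   to the file name without extension when absent).
#'
#' Data values must be 0, 1 or blank (blank = not observed); phase values
#' must be `baseline`, `intervention` or blank (blank = baseline). Without a
#' `#role` line the first variable column is taken as the outcome and the
#' remaining columns as factors.
#'
#' @param path Path to a diary CSV file.
#' @return An [nof1_diary][diary()] object.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty diary file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "date") {
    stop("diary header must start with 'date' and list at least one variable")
  }
  body <- lines[-1]
  meta <- body[startsWith(body, "#")]
  data_lines <- body[!startsWith(body, "#") & nzchar(body)]

  subject_id <- sub("\\.[^.]*$", "", basename(path))
  roles <- NULL
  for (m in meta) {
    f <- strsplit(m, ",", fixed = TRUE)[[1]]
    if (f[1] == "#subject" && length(f) >= 2) subject_id <- f[2]
    if (f[1] == "#role") {
      f <- c(f, rep("", max(0, length(header) - length(f))))
      var_cols <- setdiff(seq_along(header), which(header %in% c("date", "phase")))
      r <- f[var_cols]
      if (any(!nzchar(r))) stop("#role line must give a role for every variable column")
      roles <- stats::setNames(r, header[var_cols])
    }
  }

  df <- utils::read.csv(
    text = paste(c(lines[1], data_lines), collapse = "\n"),
    colClasses = "character", check.names = FALSE
  )
  diary(df, roles = roles, subject_id = subject_id)
}

#' Write a diary to CSV
#'
#' Serialises a diary in the format accepted by [read_diary()]; missing
#' values become blank cells, and `write_diary()` followed by
#' [read_diary()] reproduces the original diary exactly.
#'
#' @param diary An [nof1_diary][diary()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(diary, path) {
  stopifnot(inherits(diary, "nof1_diary"))
  vars <- diary$variables$name
  header <- paste(c("date", "phase", vars), collapse = ",")
  role_line <- paste(c("#role", "", diary$variables$role), collapse = ",")
  subj_line <- paste0("#subject,", diary$subject_id)
  e <- diary$entries
  rows <- character(nrow(e))
  if (nrow(e) > 0) {
    valmat <- vapply(vars, function(v) {
      x <- e[[v]]
      ifelse(is.na(x), "", as.character(x))
    }, character(nrow(e)))
    valmat <- matrix(valmat, nrow = nrow(e))
    rows <- paste(format(e$date, "%Y-%m-%d"), e$phase,
                  apply(valmat, 1, paste, collapse = ","), sep = ",")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, role_line, subj_line, rows), con)
  invisible(path)
}

#' Extract the entries belonging to one study phase
#'
#' @param diary An [nof1_diary][diary()] object.
#' @param label `"baseline"` or `"intervention"`. Days with no explicit
#'   phase are baseline, so `slice_phase(d, "baseline")` and
#'   `slice_phase(d, "intervention")` always partition the entries.
#' @return An [nof1_diary][diary()] with the same variables and only the
#'   matching days (possibly none).
#' @export
slice_phase <- function(diary, label = c("baseline", "intervention")) {
  stopifnot(inherits(diary, "nof1_diary"))
  label <- match.arg(label)
  keep <- diary$entries$phase == label
  out <- diary
  out$entries <- diary$entries[keep, , drop = FALSE]
  rownames(out$entries) <- NULL
  out
}

#' Concatenate a baseline and an intervention diary into one two-phase diary
#'
#' Utility for building full N-of-1 cycles from separately simulated or
#' recorded phases. The intervention entries are relabelled
#' `"intervention"` and, if they overlap the baseline dates, shifted so the
#' intervention starts the day after the last baseline entry.
#'
#' @param baseline,intervention [nof1_diary][diary()] objects with identical
#'   variables.
#' @return A single two-phase [nof1_diary][diary()].
#' @export
bind_phases <- function(baseline, intervention) {
  stopifnot(inherits(baseline, "nof1_diary"), inherits(intervention, "nof1_diary"))
  if (!identical(baseline$variables, intervention$variables)) {
    stop("diaries must have identical variables to be bound")
  }
  b <- baseline$entries
  i <- intervention$entries
  b$phase <- "baseline"
  i$phase <- "intervention"
  if (nrow(b) > 0 && nrow(i) > 0 && min(i$date) <= max(b$date)) {
    i$date <- i$date + as.numeric(max(b$date) - min(i$date)) + 1
  }
  d <- baseline
  d$entries <- rbind(b, i)
  rownames(d$entries) <- NULL
  d
}
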