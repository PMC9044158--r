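test_that("CSV ingestion transcribes values, blanks and roles", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "date,phase,migraine,caffeine",
    "#role,,outcome,factor",
    "2024-01-01,baseline,1,1",
    "2024-01-02,baseline,0,",
    "2024-01-03,,1,0",
    "2024-01-04,intervention,0,0",
    "2024-01-05,intervention,0,1"
  ), path)
  d <- read_diary(path)
  expect_s3_class(d, "nof1_diary")
  expect_equal(nrow(d$entries), 5)
  expect_equal(diary_variables(d, "outcome"), "migraine")
  expect_equal(diary_variables(d, "factor"), "caffeine")
  expect_true(is.na(d$entries$caffeine[2]))
  expect_equal(d$entries$migraine, c(1L, 0L, 1L, 0L, 0L))
  # blank phase defaults to baseline
  expect_equal(d$entries$phase,
               c("baseline", "baseline", "baseline", "intervention",
                 "intervention"))
})

test_that("ingestion rejects malformed files with named locations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,flare,coffee", "2024-01-01,1,0", "2024-01-02,2,0"),
             path)
  expect_error(read_diary(path), "flare.*2024-01-02")

  writeLines(c("date,flare", "2024-01-01,1", "2024-01-01,0"), path)
  expect_error(read_diary(path), "duplicate.*2024-01-01")

  writeLines(c("date,phase,flare", "2024-01-01,washout,1"), path)
  expect_error(read_diary(path), "unknown phase.*washout")

  writeLines(c("date,phase,a,b", "#role,,factor,factor",
               "2024-01-01,baseline,1,0"), path)
  expect_error(read_diary(path), "outcome")
})

test_that("write then read is the identity, including degenerate diaries", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(401)
  for (i in 1:25) {
    d <- random_diary()
    write_diary(d, path)
    expect_identical(read_diary(path), d)
  }
  # empty diary: header-only file, still re-readable
  d0 <- diary(data.frame(date = as.Date(character()), o = integer()),
              roles = c(o = "outcome"), subject_id = "empty")
  write_diary(d0, path)
  expect_identical(read_diary(path), d0)
})

test_that("missing values serialize as blank cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- diary(data.frame(date = as.Date("2024-02-01") + 0:1,
                        o = c(1L, NA)), roles = c(o = "outcome"))
  write_diary(d, path)
  lines <- readLines(path)
  expect_true(any(grepl("^2024-02-02,baseline,$", lines)))
})

test_that("role defaults apply when no #role line is present", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,a,b,c", "2024-01-01,1,0,1"), path)
  d <- read_diary(path)
  expect_equal(diary_variables(d, "outcome"), "a")
  expect_equal(diary_variables(d, "factor"), c("b", "c"))
})

test_that("phase slicing partitions the entries without loss", {
  set.seed(402)
  for (i in 1:20) {
    d <- random_diary()
    b <- slice_phase(d, "baseline")
    iv <- slice_phase(d, "intervention")
    expect_identical(b$variables, d$variables)
    combined <- rbind(b$entries, iv$entries)
    combined <- combined[order(combined$date), , drop = FALSE]
    rownames(combined) <- NULL
    expect_identical(combined, d$entries)
  }
})

test_that("a diary with no intervention span slices to an empty intervention", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:9,
                        o = rep(0:1, 5)), roles = c(o = "outcome"))
  expect_equal(nrow(slice_phase(d, "intervention")$entries), 0)
  expect_equal(nrow(slice_phase(d, "baseline")$entries), 10)
})

test_that("phase spans summarise contiguous runs", {
  d <- diary(data.frame(date = as.Date("2024-01-01") + 0:5,
                        phase = rep(c("baseline", "intervention"), each = 3),
                        o = rep(0L, 6)), roles = c(o = "outcome"))
  sp <- phase_spans(d)
  expect_equal(sp$label, c("baseline", "intervention"))
  expect_equal(sp$n_days, c(3L, 3L))
  expect_true(all(sp$start <= sp$end))
})

test_that("bind_phases shifts overlapping intervention dates and relabels", {
  base <- diary(data.frame(date = as.Date("2024-01-01") + 0:9,
                           o = rep(0:1, 5)), roles = c(o = "outcome"))
  post <- diary(data.frame(date = as.Date("2024-01-01") + 0:4,
                           o = rep(1L, 5)), roles = c(o = "outcome"))
  d <- bind_phases(base, post)
  expect_equal(nrow(d$entries), 15)
  expect_false(anyDuplicated(d$entries$date) > 0)
  expect_equal(sum(d$entries$phase == "intervention"), 5)
  expect_true(min(d$entries$date[d$entries$phase == "intervention"]) >
                max(d$entries$date[d$entries$phase == "baseline"]))
})
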