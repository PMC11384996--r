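# Trial I/O, validation, and the pre-analysis filtering rules.

test_that("a well-formed trial CSV round-trips through read_trials", {
  path <- system.file("extdata", "example_trials.csv", package = "hybridsearch")
  tt <- read_trials(path)
  expect_s3_class(tt, "trial_table")
  expect_equal(nrow(tt), 12)
  tmp <- tempfile(fileext = ".csv")
  write_trials(tt, tmp)
  tt2 <- read_trials(tmp)
  expect_equal(as.data.frame(tt2), as.data.frame(tt))
  expect_true(file.exists(paste0(tmp, ".provenance.json")))
})

test_that("rt = NA is accepted on response = none rows only", {
  df <- as.data.frame(make_trials(4))
  df$response[2] <- "none"; df$rt[2] <- NA; df$correct[2] <- NA
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE, na = "NA")
  tt <- read_trials(tmp)
  expect_true(is.na(tt$rt[2]))
  # but an answered trial with missing rt is invalid
  df2 <- as.data.frame(make_trials(4))
  df2$rt[3] <- NA
  write.csv(df2, tmp, row.names = FALSE, na = "NA")
  expect_error(read_trials(tmp), "row 3")
})

test_that("rows violating the correctness invariant are rejected with line numbers", {
  df <- as.data.frame(make_trials(5))
  df$response[4] <- "absent"   # target present + absent response => incorrect
  df$correct[4] <- TRUE        # ... but flagged correct
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE, na = "NA")
  expect_error(read_trials(tmp), "row 4.*correct inconsistent")
})

test_that("missing mandatory columns and bad units are reported", {
  df <- as.data.frame(make_trials(3))
  df$rt <- NULL
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE)
  expect_error(read_trials(tmp), "rt")
  # millisecond dialect converts on read
  df <- as.data.frame(make_trials(3, rt = 1.5))
  df$rt <- df$rt * 1000
  write.csv(df, tmp, row.names = FALSE)
  tt <- read_trials(tmp, dialect = list(rt_unit = "ms"))
  expect_equal(tt$rt, rep(1.5, 3))
})

test_that("the RT-analysis filter keeps exactly answered correct trials and counts removals", {
  df <- as.data.frame(make_trials(10))
  df$response[1:2] <- "none"; df$rt[1:2] <- NA; df$correct[1:2] <- NA
  df$response[3:5] <- "absent"; df$correct[3:5] <- FALSE
  tt <- trial_table(df)
  out <- filter_for_rt_analysis(tt)
  expect_equal(nrow(out), 5)
  prov <- provenance(out)
  last <- prov[[length(prov)]]
  expect_equal(last$removed$timeouts, 2)
  expect_equal(last$removed$incorrect, 3)
})

test_that("sub-200 ms correct responses are retained", {
  tt <- make_trials(3, rt = c(0.15, 1.0, 2.0))
  out <- filter_for_rt_analysis(tt)
  expect_equal(nrow(out), 3)
  expect_true(0.15 %in% out$rt)
})

test_that("the RT-analysis filter is idempotent and the all-correct case is the identity", {
  tt <- make_trials(8, rt = runif(8, 0.5, 3))
  once <- filter_for_rt_analysis(tt)
  twice <- filter_for_rt_analysis(once)
  expect_equal(as.data.frame(twice), as.data.frame(once), ignore_attr = TRUE)
  expect_equal(as.data.frame(once), as.data.frame(tt), ignore_attr = TRUE)
})

test_that("low-accuracy exclusion follows the mean - k*SD rule", {
  # zero SD: nobody excluded
  df <- do.call(rbind, lapply(1:20, function(i) {
    d <- as.data.frame(make_trials(10, participant_id = sprintf("p%02d", i)))
    d$response[1:3] <- "absent"; d$correct[1:3] <- FALSE
    d
  }))
  res <- exclude_low_accuracy_participants(trial_table(df))
  expect_equal(res$excluded, character(0))

  # one far-outlying participant is the unique exclusion; expected threshold
  # computed directly from the generated accuracies
  set.seed(42)
  accs <- c(pmin(0.99, rnorm(19, 0.7, 0.02)), 0.30)
  df2 <- do.call(rbind, lapply(seq_along(accs), function(i) {
    n <- 100
    n_ok <- round(accs[i] * n)
    d <- as.data.frame(make_trials(n, participant_id = sprintf("p%02d", i)))
    if (n_ok < n) {
      d$response[(n_ok + 1):n] <- "absent"
      d$correct[(n_ok + 1):n] <- FALSE
    }
    d
  }))
  realised <- tapply(df2$correct, df2$participant_id, mean)
  expected <- sort(names(realised)[realised < mean(realised) - 3 * sd(realised)])
  expect_equal(expected, "p20")  # oracle: direct computation on the inputs
  res2 <- exclude_low_accuracy_participants(trial_table(df2))
  expect_equal(res2$excluded, "p20")
  expect_false("p20" %in% res2$trials$participant_id)

  # k = 0 removes everyone below the mean; k = Inf is the identity
  res3 <- exclude_low_accuracy_participants(trial_table(df2), k = 0)
  expect_equal(res3$excluded, sort(names(realised)[realised < mean(realised)]))
  res4 <- exclude_low_accuracy_participants(trial_table(df2), k = Inf)
  expect_equal(res4$excluded, character(0))

  # a single participant has no SD
  expect_error(exclude_low_accuracy_participants(make_trials(5)), "2 participants")
})

test_that("stimulus screening discards nothing under the null", {
  tt <- make_screening_cell(n_stim = 4, n_per = 25, seed = 11)
  res <- screen_stimuli(tt)
  expect_equal(res$discarded, character(0))
  expect_equal(nrow(res$trials), nrow(tt))
})

test_that("a +3 s stimulus is the unique discard and its trials are removed", {
  tt <- make_screening_cell(shift = c(0, 0, 3, 0), seed = 12)
  res <- screen_stimuli(tt)
  expect_equal(res$discarded, "stim03")
  expect_false("stim03" %in% res$trials$stimulus_id)
  entry <- Filter(function(e) !isTRUE(e$skipped), res$log)[[1]]
  expect_gt(entry$f, 20)
  expect_lt(entry$p, 0.05)
})

test_that("at most one stimulus is discarded per cell even with two deviants", {
  tt <- make_screening_cell(shift = c(0, 1.5, 3, 0), seed = 13)
  res <- screen_stimuli(tt)
  expect_equal(res$discarded, "stim03")  # only the worse of the two
})

test_that("cells with a single stimulus are skipped with a log entry", {
  tt <- make_trials(30, stimulus_id = "only_stim", rt = runif(30, 0.5, 3))
  res <- screen_stimuli(tt)
  expect_equal(res$discarded, character(0))
  expect_true(any(vapply(res$log, function(e) isTRUE(e$skipped), logical(1))))
})
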