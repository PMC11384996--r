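# Trial-level data model, delimited-file I/O, and the filtering/screening
# rules applied to hybrid-search behavioural data before analysis.

TRIAL_COLUMNS <- c(
  "participant_id", "trial_index", "stimulus_id", "mss", "vss",
  "context_present", "target_present", "response", "rt", "correct"
)

SET_SIZE_LEVELS <- c(1L, 2L, 4L, 8L)

#' Construct a trial table
#'
#' A trial table is a validated `data.frame` of hybrid-search trials (one row
#' per trial) carrying a provenance attribute that records every filter
#' applied to it and the number of rows each removed.
#'
#' @param df data frame with columns `participant_id`, `trial_index`,
#'   `stimulus_id`, `mss`, `vss`, `context_present`, `target_present`,
#'   `response` (`"present"`, `"absent"` or `"none"`), `rt` (seconds, `NA`
#'   when `response == "none"`) and `correct` (logical, `NA` when
#'   `response == "none"`).
#' @param validate run row-level invariant checks (default `TRUE`).
#' @param t_max response deadline in seconds; answered trials must have
#'   `rt <= t_max`.
#' @return an object of class `trial_table`.
#' @export
trial_table <- function(df, validate = TRUE, t_max = 7.0) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[TRIAL_COLUMNS]
  df$participant_id <- as.character(df$participant_id)
  df$trial_index <- as.integer(df$trial_index)
  df$stimulus_id <- as.character(df$stimulus_id)
  df$mss <- as.integer(df$mss)
  df$vss <- as.integer(df$vss)
  df$context_present <- as.logical(df$context_present)
  df$target_present <- as.logical(df$target_present)
  df$response <- as.character(df$response)
  df$rt <- as.numeric(df$rt)
  df$correct <- as.logical(df$correct)
  rownames(df) <- NULL
  if (validate) {
    errs <- validate_trials(df, t_max = t_max)
    if (length(errs) > 0) {
      stopf("invalid trial rows:\n%s", paste(errs, collapse = "\n"))
    }
  }
  structure(df,
    class = c("trial_table", "data.frame"),
    provenance = list(list(step = "created", n_rows = nrow(df)))
  )
}

# Row-level invariant checks; returns a character vector of messages
# ("row <i>: <problem>"), empty when the table is valid.
validate_trials <- function(df, t_max = 7.0) {
  errs <- character(0)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) sprintf("row %d: %s", idx, msg) else character(0)
  }
  answered <- !is.na(df$response) & df$response != "none"
  errs <- c(
    errs,
    bad(is.na(df$response) | !df$response %in% c("present", "absent", "none"),
        "response must be one of present/absent/none"),
    bad(!df$mss %in% SET_SIZE_LEVELS, "mss must be one of 1, 2, 4, 8"),
    bad(!df$vss %in% SET_SIZE_LEVELS, "vss must be one of 1, 2, 4, 8"),
    bad(is.na(df$context_present), "context_present must be TRUE/FALSE"),
    bad(is.na(df$target_present), "target_present must be TRUE/FALSE"),
    bad(answered & is.na(df$rt), "answered trial with missing rt"),
    bad(answered & !is.na(df$rt) & (df$rt <= 0 | df$rt > t_max),
        sprintf("rt must lie in (0, %g] seconds", t_max)),
    bad(answered & is.na(df$correct), "answered trial with missing correct"),
    bad(answered & !is.na(df$correct) &
          df$correct != xor(df$response == "present", !df$target_present),
        "correct inconsistent with response and target_present")
  )
  errs
}

#' Provenance of a trial table
#'
#' Returns the list of processing steps applied to the table, each with the
#' counts of rows removed, so every filtered dataset documents its history.
#'
#' @param trials a [trial_table()].
#' @return list of provenance records.
#' @export
provenance <- function(trials) attr(trials, "provenance")

add_provenance <- function(trials, step, removed = list(), n_before, n_after) {
  prov <- c(attr(trials, "provenance"),
            list(list(step = step, removed = removed,
                      n_before = n_before, n_after = n_after)))
  attr(trials, "provenance") <- prov
  trials
}

# Subset rows while keeping class and provenance intact.
keep_rows <- function(trials, keep) {
  out <- as.data.frame(trials)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(trials), provenance = attr(trials, "provenance"))
}

#' Read a trial CSV
#'
#' Reads a comma-separated UTF-8 file with a header row into a validated
#' [trial_table()]. Booleans are accepted as `0/1` or `true/false`; the RT
#' column is in seconds unless `dialect$rt_unit = "ms"`.
#'
#' @param path path to the CSV file.
#' @param dialect optional list: `rt_unit` (`"s"` default, or `"ms"`),
#'   `columns` (named character vector mapping file column names onto the
#'   canonical ones, e.g. `c(subject = "participant_id")`).
#' @return a [trial_table()].
#' @export
read_trials <- function(path, dialect = list()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), encoding = "UTF-8")
  cols <- dialect$columns
  if (!is.null(cols)) {
    hit <- names(raw) %in% names(cols)
    names(raw)[hit] <- unname(cols[names(raw)[hit]])
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  to_logical <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(as.character(x))
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "t")] <- TRUE
    out[x %in% c("0", "false", "f")] <- FALSE
    out
  }
  raw$context_present <- to_logical(raw$context_present)
  raw$target_present <- to_logical(raw$target_present)
  raw$correct <- to_logical(raw$correct)
  rt_chr <- as.character(raw$rt)
  rt <- suppressWarnings(as.numeric(rt_chr))
  unparseable <- which(!is.na(rt_chr) & is.na(rt))
  if (length(unparseable) > 0) {
    stopf("unparseable rt value(s) on row(s): %s",
          paste(unparseable, collapse = ", "))
  }
  if (identical(dialect$rt_unit %||% "s", "ms")) rt <- rt / 1000
  raw$rt <- rt
  trial_table(raw)
}

#' Write a trial table with its provenance sidecar
#'
#' Writes the trials as CSV and the accumulated filter provenance as a JSON
#' sidecar (`<path>.provenance.json`).
#'
#' @param trials a [trial_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "NA")
  jsonlite::write_json(provenance(trials),
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Filter trials for RT analysis
#'
#' Applies the standard RT-analysis filter: trials with no response within
#' the deadline are excluded, incorrect trials are excluded, and very short
#' responses (sub-200 ms) are retained. The counts removed by each rule are
#' recorded in the table's provenance.
#'
#' @param trials a [trial_table()].
#' @return the filtered [trial_table()].
#' @export
filter_for_rt_analysis <- function(trials) {
  n0 <- nrow(trials)
  timeout <- trials$response == "none"
  incorrect <- !timeout & !trials$correct
  keep <- !timeout & !incorrect
  out <- keep_rows(trials, keep)
  if (nrow(out) == 0) warnf("RT-analysis filter removed every trial")
  add_provenance(out, "filter_for_rt_analysis",
                 removed = list(timeouts = sum(timeout),
                                incorrect = sum(incorrect)),
                 n_before = n0, n_after = nrow(out))
}

#' Exclude participants with outlying low accuracy
#'
#' Removes participants whose overall accuracy (computed on the raw,
#' unfiltered data; unanswered trials count as errors) falls more than `k`
#' standard deviations below the across-participant mean. When the
#' across-participant SD is zero nobody is excluded.
#'
#' @param trials a [trial_table()].
#' @param k number of standard deviations (default 3).
#' @return list with elements `trials` (filtered table) and `excluded`
#'   (sorted character vector of excluded participant ids).
#' @export
exclude_low_accuracy_participants <- function(trials, k = 3) {
  acc <- tapply(trials$correct %in% TRUE, trials$participant_id, mean)
  if (length(acc) < 2) stopf("need at least 2 participants to compute the accuracy SD")
  mu <- mean(acc)
  sdev <- stats::sd(acc)
  excluded <- if (sdev == 0) character(0) else sort(names(acc)[acc < mu - k * sdev])
  out <- keep_rows(trials, !trials$participant_id %in% excluded)
  out <- add_provenance(out, "exclude_low_accuracy_participants",
                        removed = list(participants = as.list(excluded),
                                       trials = nrow(trials) - nrow(out)),
                        n_before = nrow(trials), n_after = nrow(out))
  list(trials = out, excluded = excluded)
}

#' Screen stimuli for condition-level RT outliers
#'
#' Within each condition cell (context x MSS x VSS x target presence), a
#' one-way ANOVA of correct-trial RT on stimulus identity is run. If the F
#' statistic exceeds `f_threshold` with p below `alpha`, Tukey HSD post-hoc
#' comparisons are computed and the single stimulus whose mean RT deviates
#' most from the mean of the remaining stimuli in the cell is discarded (at
#' most one stimulus per cell, to preserve design balance). All trials of a
#' discarded stimulus are removed.
#'
#' @param trials a [trial_table()].
#' @param f_threshold minimum F statistic to trigger post-hoc screening
#'   (default 20).
#' @param alpha significance level for the ANOVA and Tukey HSD (default 0.05).
#' @return list with elements `trials` (screened table), `discarded`
#'   (character vector of stimulus ids) and `log` (per-cell records).
#' @export
screen_stimuli <- function(trials, f_threshold = 20, alpha = 0.05) {
  analysed <- trials$response != "none" & trials$correct %in% TRUE
  df <- as.data.frame(trials)[analysed, , drop = FALSE]
  cell <- interaction(df$context_present, df$mss, df$vss, df$target_present,
                      drop = TRUE)
  discarded <- character(0)
  log <- list()
  for (cl in levels(cell)) {
    sub <- df[cell == cl, , drop = FALSE]
    counts <- table(sub$stimulus_id)
    usable <- names(counts)[counts >= 2]
    if (length(usable) < 2) {
      log[[cl]] <- list(cell = cl, skipped = TRUE,
                        reason = "fewer than 2 stimuli with >= 2 RTs")
      next
    }
    sub <- sub[sub$stimulus_id %in% usable, , drop = FALSE]
    sub$stimulus_id <- factor(sub$stimulus_id)
    fit <- stats::aov(rt ~ stimulus_id, data = sub)
    tab <- summary(fit)[[1]]
    fval <- tab[["F value"]][1]
    pval <- tab[["Pr(>F)"]][1]
    entry <- list(cell = cl, skipped = FALSE, f = fval, p = pval,
                  discarded = NA_character_)
    if (is.finite(fval) && fval > f_threshold && pval < alpha) {
      tukey <- stats::TukeyHSD(fit, conf.level = 1 - alpha)
      means <- tapply(sub$rt, sub$stimulus_id, mean)
      # largest absolute deviation of a stimulus mean from the mean of the
      # other stimuli in the cell; exact ties (a two-stimulus cell is
      # perfectly symmetric) go to the slower stimulus, since RT screening
      # targets abnormally slow images
      dev <- vapply(seq_along(means), function(i) {
        abs(means[i] - mean(means[-i]))
      }, numeric(1))
      tied <- which(dev > max(dev) - 1e-9)
      worst <- names(means)[tied[which.max(means[tied])]]
      discarded <- c(discarded, worst)
      entry$discarded <- worst
      entry$tukey <- tukey$stimulus_id
    }
    log[[cl]] <- entry
  }
  out <- keep_rows(trials, !trials$stimulus_id %in% discarded)
  out <- add_provenance(out, "screen_stimuli",
                        removed = list(stimuli = as.list(discarded),
                                       trials = nrow(trials) - nrow(out)),
                        n_before = nrow(trials), n_after = nrow(out))
  list(trials = out, discarded = discarded, log = log)
}
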