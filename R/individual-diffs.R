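# Individual-difference measures: Cowan's K from change detection, signal
# detection theory d-prime and criterion c from go/no-go responding, and
# their correlations with hybrid-search slopes and intercepts.

#' Cowan's K working-memory capacity estimate
#'
#' `K = N * (hit rate - false-alarm rate)` for a single-probe change
#' detection task at set size N. Negative estimates are allowed (they signal
#' below-chance responding) and bounded by `+/- N`.
#'
#' @param hit_rate proportion of change trials answered "change".
#' @param fa_rate proportion of no-change trials answered "change".
#' @param set_size number of items in the memory display.
#' @return capacity estimate in items (vectorised).
#' @export
cowan_k <- function(hit_rate, fa_rate, set_size) {
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1),
            all(fa_rate >= 0 & fa_rate <= 1),
            all(set_size >= 1))
  set_size * (hit_rate - fa_rate)
}

#' Signal detection theory measures
#'
#' `d' = z(H) - z(FA)` and criterion `c = -(z(H) + z(FA)) / 2`, with `z` the
#' standard normal quantile. When counts are supplied, extreme rates (0 or
#' 1) are adjusted by the log-linear correction (add 0.5 to each count and 1
#' to each trial total) before transforming; non-extreme rates are used
#' as-is. With rates only, extreme values are an error.
#'
#' @param hits hit count (with `n_signal`) or hit rate (without).
#' @param fas false-alarm count (with `n_noise`) or false-alarm rate.
#' @param n_signal,n_noise trial totals; omit to pass rates directly.
#' @param correction `"loglinear"` (default, needs counts) or `"none"`.
#' @return list: `d_prime`, `criterion_c`, `hit_rate`, `fa_rate`,
#'   `corrected` (logical, per rate pair).
#' @export
sdt_measures <- function(hits, fas, n_signal = NULL, n_noise = NULL,
                         correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (is.null(n_signal) != is.null(n_noise)) {
    stopf("supply both n_signal and n_noise, or neither")
  }
  if (!is.null(n_signal)) {
    if (any(n_signal <= 0) || any(n_noise <= 0)) stopf("zero trials")
    H <- hits / n_signal
    FA <- fas / n_noise
    extreme <- H %in% c(0, 1) | FA %in% c(0, 1)
    if (correction == "loglinear") {
      H <- ifelse(extreme, (hits + 0.5) / (n_signal + 1), H)
      FA <- ifelse(extreme, (fas + 0.5) / (n_noise + 1), FA)
    } else if (any(extreme)) {
      stopf("extreme rate (0 or 1) without correction")
    }
  } else {
    H <- hits
    FA <- fas
    extreme <- H %in% c(0, 1) | FA %in% c(0, 1)
    if (any(extreme)) {
      stopf("extreme rate (0 or 1); supply counts so the log-linear correction can apply")
    }
  }
  zH <- stats::qnorm(H)
  zFA <- stats::qnorm(FA)
  list(d_prime = zH - zFA, criterion_c = -(zH + zFA) / 2,
       hit_rate = H, fa_rate = FA, corrected = extreme)
}

#' Per-participant capacity measures from a change-detection table
#'
#' Hit and false-alarm rates are computed per participant and set size;
#' Cowan's K is estimated per set size and averaged across the set sizes
#' presented.
#'
#' @param cdt output of [generate_cdt()] or a table with columns
#'   `participant_id`, `set_size`, `change_present`, `response`.
#' @return data frame: one row per participant with `k`, and per-set-size
#'   hit/false-alarm rates.
#' @export
cdt_capacity <- function(cdt) {
  rows <- lapply(split(cdt, cdt$participant_id), function(sub) {
    per_size <- lapply(split(sub, sub$set_size), function(s) {
      h <- mean(s$response[s$change_present])
      fa <- mean(s$response[!s$change_present])
      data.frame(set_size = s$set_size[1], hit_rate = h, fa_rate = fa,
                 k = cowan_k(h, fa, s$set_size[1]))
    })
    ps <- do.call(rbind, per_size)
    data.frame(participant_id = sub$participant_id[1],
               k = mean(ps$k),
               hit_rate = mean(ps$hit_rate), fa_rate = mean(ps$fa_rate))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-participant SDT measures from a go/no-go table
#'
#' Go trials are the signal (a response is a hit), no-go responses are false
#' alarms; under this convention liberal responding yields negative
#' criterion c.
#'
#' @param gng output of [generate_gng()] or a table with columns
#'   `participant_id`, `is_go`, `responded`.
#' @return data frame: one row per participant with `d_prime`,
#'   `criterion_c`, rates and counts.
#' @export
gng_measures <- function(gng) {
  rows <- lapply(split(gng, gng$participant_id), function(sub) {
    n_go <- sum(sub$is_go); n_nogo <- sum(!sub$is_go)
    hits <- sum(sub$responded[sub$is_go])
    fas <- sum(sub$responded[!sub$is_go])
    m <- sdt_measures(hits, fas, n_go, n_nogo)
    data.frame(participant_id = sub$participant_id[1],
               d_prime = m$d_prime, criterion_c = m$criterion_c,
               hit_rate = m$hit_rate, fa_rate = m$fa_rate,
               n_signal = n_go, n_noise = n_nogo, corrected = m$corrected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate capacity measures with search statistics
#'
#' Pearson correlations between each individual-difference measure and each
#' per-participant search statistic (slope, intercept), separately per
#' (axis, context, form) cell of the curve fits. Two-sided p-values come
#' from the t transform of r.
#'
#' @param measures data frame with `participant_id` and measure columns
#'   (e.g. `k`, `criterion_c`).
#' @param fits output of [participant_setsize_curves()].
#' @param measure_vars measure column names to correlate.
#' @param stat_vars curve-fit statistics to correlate (default slope and
#'   intercept).
#' @return data frame: one row per cell x measure x statistic with `r`,
#'   `p`, `r_squared`, `n`.
#' @export
correlate_with_search <- function(measures, fits,
                                  measure_vars = c("k", "criterion_c"),
                                  stat_vars = c("slope", "intercept")) {
  measure_vars <- intersect(measure_vars, names(measures))
  fits <- as.data.frame(fits)
  key <- interaction(fits$axis, fits$context, fits$form, drop = TRUE)
  out <- list()
  for (kl in levels(key)) {
    sub <- fits[key == kl, ]
    merged <- merge(sub, measures, by = "participant_id")
    if (nrow(merged) < 4) {
      warnf("cell %s: fewer than 4 matched participants; skipped", kl)
      next
    }
    for (mv in measure_vars) {
      for (sv in stat_vars) {
        x <- merged[[mv]]; y <- merged[[sv]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          warnf("cell %s: zero variance in %s or %s; skipped", kl, mv, sv)
          next
        }
        ct <- stats::cor.test(x, y, method = "pearson")
        out[[length(out) + 1]] <- data.frame(
          axis = sub$axis[1], context = sub$context[1], form = sub$form[1],
          measure = mv, statistic = sv,
          r = unname(ct$estimate), p = ct$p.value,
          r_squared = unname(ct$estimate)^2, n = nrow(merged)
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
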