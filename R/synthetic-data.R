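# Seeded generators for hybrid-search, change-detection and go/no-go trial
# tables with the statistical structure the analyses assume: a balanced
# set-size design, DDM-generated choices and RTs, participant heterogeneity
# as a random shift of the non-decision time, and population-level capacity
# (Cowan's K) and response-bias (criterion c) distributions.

#' Generator configuration
#'
#' Defaults emulate the reference experimental design: 110 participants, 112
#' hybrid-search trials each over set sizes \{1, 2, 4, 8\} crossed for memory
#' and visual sets, 50% context-present and 50% target-present, a 7 s
#' response deadline; a 120-trial change-detection task at set sizes 4 and 6
#' with population capacity K ~ N(2.31, 0.82); and a 150-trial go/no-go task
#' with a 4:1 go ratio and population criterion c ~ N(-0.23, 0.58).
#'
#' Participant heterogeneity enters as a normal additive shift on the
#' non-decision time with SD `participant_sd`; the default (0.5625 s, before
#' truncation at a strictly positive effective t0) was set by
#' [calibrate_participant_sd()] at the full design size so the
#' random-intercept share of RT variance (ICC) is close to 0.15.
#'
#' @param n_participants number of participants (default 110).
#' @param n_trials hybrid-search trials per participant (default 112).
#' @param set_sizes set-size levels for both MSS and VSS.
#' @param spec a [hybrid_ddm_spec()] used as generative mechanism.
#' @param participant_sd SD (seconds) of the per-participant non-decision
#'   shift.
#' @param dt Euler step for bulk trial synthesis, seconds.
#' @param stimulus_outlier optional `list(stimulus_id =, shift =)` adding
#'   `shift` seconds to every RT of one stimulus (capped just under the
#'   deadline), for exercising the screening rule.
#' @param low_accuracy_participant optional `list(participant =, accuracy =)`
#'   rewriting that participant's responses to a fixed accuracy level, for
#'   exercising the exclusion rule.
#' @param cdt list: `n_trials`, `set_sizes`, `change_prob`, `k_mean`, `k_sd`,
#'   `guess_rate`.
#' @param gng list: `n_trials`, `go_ratio`, `c_mean`, `c_sd`, `dprime_mean`,
#'   `dprime_sd`.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 110, n_trials = 112,
                             set_sizes = c(1L, 2L, 4L, 8L),
                             spec = hybrid_ddm_spec(),
                             participant_sd = 0.5625,
                             dt = 0.005,
                             stimulus_outlier = NULL,
                             low_accuracy_participant = NULL,
                             cdt = list(n_trials = 120, set_sizes = c(4, 6),
                                        change_prob = 0.5,
                                        k_mean = 2.31, k_sd = 0.82,
                                        guess_rate = 0.1),
                             gng = list(n_trials = 150, go_ratio = 4,
                                        c_mean = -0.23, c_sd = 0.58,
                                        dprime_mean = 2.5, dprime_sd = 0.6)) {
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 set_sizes = as.integer(set_sizes), spec = spec,
                 participant_sd = participant_sd, dt = dt,
                 stimulus_outlier = stimulus_outlier,
                 low_accuracy_participant = low_accuracy_participant,
                 cdt = cdt, gng = gng),
            class = "generator_config")
}

# The shared 112-trial design: every {MSS, VSS} pair appears n_trials/16
# times; within each pair the four (context, target) combinations are
# assigned as evenly as possible, with the leftover rotated across pairs so
# that context and target are each present on exactly half of all trials.
# Every trial carries a unique stimulus id shared by all participants.
build_design <- function(n_trials, set_sizes) {
  pairs <- expand.grid(mss = set_sizes, vss = set_sizes)
  per_pair <- n_trials %/% nrow(pairs)
  combos <- expand.grid(context_present = c(FALSE, TRUE),
                        target_present = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    # rotate which combos receive the remainder so totals stay balanced
    idx <- ((seq_len(per_pair) + j - 1) %% 4) + 1
    data.frame(
      mss = pairs$mss[j], vss = pairs$vss[j],
      context_present = combos$context_present[idx],
      target_present = combos$target_present[idx]
    )
  })
  design <- do.call(rbind, rows)
  design$stimulus_id <- sprintf("stim_%03d", seq_len(nrow(design)))
  design
}

#' Generate a synthetic hybrid-search experiment
#'
#' Each trial's response and RT are drawn from the hybrid DDM mapped for its
#' condition cell, with the participant's non-decision shift added; paths
#' unabsorbed at the deadline become `response = "none"`. Correctness is
#' derived from the response versus target presence. All participants see
#' the same stimulus set in an independently randomised order.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a [trial_table()].
#' @export
generate_experiment <- function(config = generator_config(), seed = 1) {
  spec <- config$spec
  design <- build_design(config$n_trials, config$set_sizes)
  with_seed(seed, {
    shifts <- stats::rnorm(config$n_participants, 0, config$participant_sd)
    # keep every participant's effective t0 strictly positive
    shifts <- pmax(shifts, -spec$t0 + 0.02)
    per_participant <- lapply(seq_len(config$n_participants), function(i) {
      ord <- sample.int(nrow(design))
      d <- design[ord, , drop = FALSE]
      p <- map_condition_vec(spec, d$mss, d$vss, d$context_present,
                             d$target_present)
      m <- .sim_ddm_cpp(p$mu, p$B, p$t0 + shifts[i], spec$sigma, spec$lambda,
                        spec$t_max, config$dt)
      data.frame(
        participant_id = sprintf("p%03d", i),
        trial_index = seq_len(nrow(d)),
        stimulus_id = d$stimulus_id,
        mss = d$mss, vss = d$vss,
        context_present = d$context_present,
        target_present = d$target_present,
        response = ifelse(is.na(m[, 1]), "none",
                          ifelse(m[, 1] == 1, "present", "absent")),
        rt = m[, 2]
      )
    })
    df <- do.call(rbind, per_participant)

    out_cfg <- config$stimulus_outlier
    if (!is.null(out_cfg)) {
      hit <- df$stimulus_id == out_cfg$stimulus_id & !is.na(df$rt)
      df$rt[hit] <- pmin(df$rt[hit] + out_cfg$shift, spec$t_max - 0.01)
    }
    low_cfg <- config$low_accuracy_participant
    if (!is.null(low_cfg)) {
      hit <- which(df$participant_id == low_cfg$participant &
                     df$response != "none")
      ok <- stats::runif(length(hit)) < low_cfg$accuracy
      correct_resp <- ifelse(df$target_present[hit], "present", "absent")
      wrong_resp <- ifelse(df$target_present[hit], "absent", "present")
      df$response[hit] <- ifelse(ok, correct_resp, wrong_resp)
    }

    df$correct <- ifelse(df$response == "none", NA,
                         xor(df$response == "present", !df$target_present))
    tt <- trial_table(df, t_max = spec$t_max)
    attr(tt, "provenance") <- list(list(
      step = "generate_experiment", seed = seed,
      n_participants = config$n_participants, n_trials = config$n_trials,
      participant_sd = config$participant_sd, dt = config$dt,
      spec = unclass(spec)[c("mu0", "gamma", "delta", "a0", "a1", "t0",
                             "lambda", "drift_form")]
    ))
    tt
  })
}

#' Calibrate the participant heterogeneity to a target ICC
#'
#' Tunes `participant_sd` by bisection so that a random-intercept mixed model
#' `rt ~ vss * context + (1 | participant)` fitted to the generated (correct,
#' answered, target-present) trials attains a requested intraclass
#' correlation. A reduced participant count keeps the search fast; the
#' returned value is meant to be frozen into [generator_config()].
#'
#' @param target_icc requested intraclass correlation (default 0.15).
#' @param config base [generator_config()].
#' @param n_participants participants per probe generation (default 40).
#' @param seed integer seed; every probe reuses the same seed (common random
#'   numbers), so the bisection target is a deterministic function of the SD.
#' @param tol bisection tolerance on the achieved ICC.
#' @param max_iter bisection iterations.
#' @return list: `participant_sd`, `achieved_icc`, `trace` (data frame of
#'   probes).
#' @export
calibrate_participant_sd <- function(target_icc = 0.15,
                                     config = generator_config(),
                                     n_participants = 40, seed = 1,
                                     tol = 0.005, max_iter = 12) {
  probe <- function(sd) {
    cfg <- config
    cfg$n_participants <- n_participants
    cfg$participant_sd <- sd
    tt <- generate_experiment(cfg, seed = seed)
    tt <- filter_for_rt_analysis(tt)
    tt <- keep_rows(tt, tt$target_present)
    fit <- fit_random_intercept_lmm(tt, rt ~ vss * context_present,
                                    group = "participant_id")
    fit$icc
  }
  lo <- 0; hi <- 1
  trace <- data.frame(sd = numeric(0), icc = numeric(0))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    icc <- probe(mid)
    trace <- rbind(trace, data.frame(sd = mid, icc = icc))
    if (abs(icc - target_icc) < tol) break
    if (icc < target_icc) lo <- mid else hi <- mid
  }
  list(participant_sd = mid, achieved_icc = icc, trace = trace)
}

#' Generate a synthetic change-detection task
#'
#' Per participant a true capacity K is drawn from the configured normal
#' (truncated at 0). On each trial of set size N the probed item is in
#' memory with probability `min(1, K/N)`; remembered probes are answered
#' correctly, unremembered ones are guessed "change" at the configured
#' guessing rate. This is the standard single-probe model that Cowan's
#' formula `K = N (H - FA)` inverts.
#'
#' @param config a [generator_config()] (fields under `cdt`).
#' @param seed integer seed.
#' @return data frame: `participant_id`, `trial_index`, `set_size`,
#'   `change_present`, `response` (logical "change" report), `true_k`.
#' @export
generate_cdt <- function(config = generator_config(), seed = 1) {
  cc <- config$cdt
  with_seed(seed, {
    per_size <- cc$n_trials / length(cc$set_sizes)
    rows <- lapply(seq_len(config$n_participants), function(i) {
      k <- max(0, stats::rnorm(1, cc$k_mean, cc$k_sd))
      set_size <- rep(cc$set_sizes, each = per_size)
      change <- stats::runif(cc$n_trials) < cc$change_prob
      p_mem <- pmin(1, k / set_size)
      # hit = remembered + guessed; false alarm = guessed only
      p_change <- ifelse(change,
                         p_mem + (1 - p_mem) * cc$guess_rate,
                         (1 - p_mem) * cc$guess_rate)
      data.frame(participant_id = sprintf("p%03d", i),
                 trial_index = seq_len(cc$n_trials),
                 set_size = set_size, change_present = change,
                 response = stats::runif(cc$n_trials) < p_change,
                 true_k = k)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic go/no-go task
#'
#' Per participant, sensitivity d' and criterion c are drawn from the
#' configured normals and responses follow the equal-variance SDT model:
#' P(respond | go) = Phi(d'/2 - c), P(respond | no-go) = Phi(-d'/2 - c).
#'
#' @param config a [generator_config()] (fields under `gng`).
#' @param seed integer seed.
#' @return data frame: `participant_id`, `trial_index`, `is_go`,
#'   `responded`, `true_dprime`, `true_c`.
#' @export
generate_gng <- function(config = generator_config(), seed = 1) {
  gg <- config$gng
  n_go <- round(gg$n_trials * gg$go_ratio / (gg$go_ratio + 1))
  with_seed(seed, {
    rows <- lapply(seq_len(config$n_participants), function(i) {
      dp <- max(0.2, stats::rnorm(1, gg$dprime_mean, gg$dprime_sd))
      cc <- stats::rnorm(1, gg$c_mean, gg$c_sd)
      is_go <- sample(rep(c(TRUE, FALSE), c(n_go, gg$n_trials - n_go)))
      p_resp <- ifelse(is_go, stats::pnorm(dp / 2 - cc),
                       stats::pnorm(-dp / 2 - cc))
      data.frame(participant_id = sprintf("p%03d", i),
                 trial_index = seq_len(gg$n_trials),
                 is_go = is_go,
                 responded = stats::runif(gg$n_trials) < p_resp,
                 true_dprime = dp, true_c = cc)
    })
    do.call(rbind, rows)
  })
}

#' Write generator outputs with a manifest
#'
#' Writes a data frame as CSV together with a JSON manifest recording the
#' seed and configuration summary, so every downstream number is traceable.
#'
#' @param df data frame to write.
#' @param path output CSV path.
#' @param seed seed used to generate `df`.
#' @param config the [generator_config()] used.
#' @return `path`, invisibly.
#' @export
write_generated <- function(df, path, seed, config) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "NA")
  manifest <- list(
    seed = seed,
    n_participants = config$n_participants,
    n_trials = config$n_trials,
    participant_sd = config$participant_sd,
    spec = unclass(config$spec)[c("mu0", "gamma", "delta", "a0", "a1",
                                  "t0", "lambda", "drift_form")]
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
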