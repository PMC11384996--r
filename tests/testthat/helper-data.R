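# Fixture builders shared across test files. Everything is generated in
# code; no stored data beyond the 12-row example CSV under inst/extdata.

# A minimal valid trial data frame; fields can be overridden per test.
make_trials <- function(n = 10, participant_id = "p1", mss = 1L, vss = 1L,
                        context_present = FALSE, target_present = TRUE,
                        response = "present", rt = 1.0, correct = NULL,
                        stimulus_id = NULL) {
  if (is.null(correct)) {
    correct <- ifelse(response == "none", NA,
                      xor(response == "present", !target_present))
  }
  df <- data.frame(
    participant_id = participant_id,
    trial_index = seq_len(n),
    stimulus_id = stimulus_id %||% sprintf("s%02d", seq_len(n)),
    mss = mss, vss = vss,
    context_present = context_present, target_present = target_present,
    response = response,
    rt = ifelse(response == "none", NA_real_, rt),
    correct = correct
  )
  trial_table(df)
}

# One condition cell with n_stim stimuli x n_per RTs each, for the
# stimulus-screening ANOVA; `shift` adds seconds to selected stimuli.
make_screening_cell <- function(n_stim = 4, n_per = 25, mean_rt = 1.5,
                                sd_rt = 0.3, shift = numeric(n_stim),
                                seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_stim), function(s) {
    data.frame(
      participant_id = sprintf("p%02d", seq_len(n_per)),
      trial_index = seq_len(n_per),
      stimulus_id = sprintf("stim%02d", s),
      mss = 1L, vss = 1L, context_present = FALSE, target_present = TRUE,
      response = "present",
      rt = pmin(rnorm(n_per, mean_rt + shift[s], sd_rt), 6.9),
      correct = TRUE
    )
  }))
  rows$rt <- pmax(rows$rt, 0.05)
  trial_table(rows)
}

# Gaussian random-intercept data for the mixed-model tests.
make_lmm_data <- function(n_p = 30, n_t = 40, intercept = 1.23,
                          beta_vss = 0.12, beta_ctx = 0.49,
                          beta_inter = 0, sd_b = 0.3, sd_e = 0.7) {
  d <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_p)),
                   t = seq_len(n_t))
  d$vss <- sample(c(1, 2, 4, 8), nrow(d), TRUE)
  d$context_present <- sample(c(TRUE, FALSE), nrow(d), TRUE)
  b <- rnorm(n_p, 0, sd_b)
  d$rt <- intercept + beta_vss * d$vss + beta_ctx * d$context_present +
    beta_inter * d$vss * d$context_present +
    b[as.integer(factor(d$participant_id))] + rnorm(nrow(d), 0, sd_e)
  d
}

# Numerical CDF of the FPT density at one boundary, for KS-style checks.
wfpt_cdf_fun <- function(params, upper = TRUE, dt = 2e-4) {
  g <- seq(0, params$t_max, by = dt)
  dens <- wfpt_density(g, params, upper)
  p_bound <- sum(dens) * dt
  cdf <- cumsum(dens) * dt / p_bound
  function(x) approx(g, cdf, xout = x, rule = 2)$y
}

ks_distance <- function(rts, cdf_fun) {
  rts <- sort(rts)
  theo <- cdf_fun(rts)
  emp_hi <- seq_along(rts) / length(rts)
  emp_lo <- (seq_along(rts) - 1) / length(rts)
  max(pmax(abs(theo - emp_hi), abs(theo - emp_lo)))
}
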