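# Curve fits, mixed models, likelihood-ratio tests and AIC form comparison.

test_that("exact linear and logarithmic fixtures are fitted perfectly", {
  x <- c(1, 2, 4, 8)
  d_lin <- data.frame(participant_id = "p1", mss = 4, vss = x,
                      context_present = FALSE, rt = 0.13 * x + 1.35)
  f <- as.data.frame(participant_setsize_curves(d_lin, axis = "vss"))
  lin <- f[f$form == "linear", ]
  expect_equal(lin$slope, 0.13)
  expect_equal(lin$intercept, 1.35)
  expect_equal(lin$r_squared, 1)

  d_log <- data.frame(participant_id = "p1", mss = x, vss = 4,
                      context_present = FALSE, rt = 0.40 * log(x) + 1.28)
  f2 <- as.data.frame(participant_setsize_curves(d_log, axis = "mss"))
  lg <- f2[f2$form == "log", ]
  expect_equal(lg$slope, 0.40)
  expect_equal(lg$intercept, 1.28)
  expect_equal(lg$r_squared, 1)

  # constant RT: zero slope under both forms
  d_const <- data.frame(participant_id = "p1", mss = 4, vss = x,
                        context_present = FALSE, rt = 1.5)
  f3 <- as.data.frame(participant_setsize_curves(d_const, axis = "vss"))
  expect_equal(f3$slope, c(0, 0))
})

test_that("curve fits satisfy the OLS normal equations", {
  set.seed(71)
  x <- rep(c(1, 2, 4, 8), each = 5)
  d <- data.frame(participant_id = "p1", mss = 4, vss = x,
                  context_present = TRUE, rt = 1 + 0.1 * x + rnorm(20, 0, 0.2))
  f <- as.data.frame(participant_setsize_curves(d, axis = "vss"))
  lin <- f[f$form == "linear", ]
  means <- tapply(d$rt, d$vss, mean)
  xs <- as.numeric(names(means))
  resid <- as.numeric(means) - (lin$intercept + lin$slope * xs)
  expect_lt(abs(sum(resid)), 1e-10)
  expect_lt(abs(sum(resid * xs)), 1e-10)
})

test_that("participants with fewer than two levels are skipped", {
  d <- data.frame(participant_id = "p1", mss = 4, vss = 4,
                  context_present = FALSE, rt = c(1, 1.2))
  f <- participant_setsize_curves(d, axis = "vss")
  expect_equal(nrow(f), 0)
  expect_length(attr(f, "skipped"), 1)  # the single-level participant is logged
})

test_that("aggregation reports mean and SEM per cell", {
  f <- data.frame(participant_id = c("a", "b"), axis = "vss", context = FALSE,
                  form = "linear", slope = c(0.1, 0.2),
                  intercept = c(1, 1), r_squared = c(1, 1), n_points = 4)
  agg <- aggregate_curves(f)
  expect_equal(agg$slope_mean, 0.15)
  expect_equal(agg$slope_sem, 0.05)
  f2 <- f; f2$slope <- c(0.1, 0.1)
  expect_equal(aggregate_curves(f2)$slope_sem, 0)
})

test_that("the ML random-intercept LMM agrees with an independent reference fit", {
  set.seed(72)
  d <- make_lmm_data(n_p = 25, n_t = 30)
  own <- fit_random_intercept_lmm(d, rt ~ vss * context_present)
  ref <- lme4::lmer(rt ~ vss * context_present + (1 | participant_id),
                    data = d, REML = FALSE)
  expect_equal(own$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
  expect_equal(unname(own$fixed_effects$estimate),
               unname(lme4::fixef(ref)), tolerance = 1e-5)
  expect_equal(own$aic, stats::AIC(ref), tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(own$icc, vc$vcov[1] / sum(vc$vcov), tolerance = 1e-4)
})

test_that("zero participant variance collapses the LMM onto OLS", {
  set.seed(73)
  d <- make_lmm_data(n_p = 20, n_t = 30, sd_b = 0)
  f <- fit_random_intercept_lmm(d, rt ~ vss * context_present)
  expect_lt(f$icc, 0.02)
  ols <- stats::lm(rt ~ vss * context_present, data = d)
  expect_equal(unname(f$fixed_effects$estimate), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("LMM invariances hold: relabeling and RT translation", {
  set.seed(74)
  d <- make_lmm_data(n_p = 15, n_t = 20)
  f1 <- fit_random_intercept_lmm(d, rt ~ vss * context_present)
  d2 <- d
  d2$participant_id <- factor(d2$participant_id,
                              levels = sample(unique(d2$participant_id)))
  f2 <- fit_random_intercept_lmm(d2, rt ~ vss * context_present)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-8)
  d3 <- d; d3$rt <- d3$rt + 5
  f3 <- fit_random_intercept_lmm(d3, rt ~ vss * context_present)
  expect_equal(f3$fixed_effects$estimate[1],
               f1$fixed_effects$estimate[1] + 5, tolerance = 1e-6)
  expect_equal(f3$fixed_effects$estimate[-1],
               f1$fixed_effects$estimate[-1], tolerance = 1e-6)
})

test_that("a singular design is rejected with the aliased term named", {
  d <- make_lmm_data(n_p = 10, n_t = 10)
  d$vss2 <- d$vss
  expect_error(fit_random_intercept_lmm(d, rt ~ vss + vss2), "vss2")
})

test_that("the likelihood-ratio test behaves at its anchors", {
  set.seed(75)
  d <- make_lmm_data(n_p = 20, n_t = 30)
  f0 <- fit_random_intercept_lmm(d, rt ~ context_present)
  f1 <- fit_random_intercept_lmm(d, rt ~ vss * context_present)
  same <- likelihood_ratio_test(f1, f1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_equal(lrt$df, 2)
  expect_gt(lrt$chi2, 0)
  expect_lt(lrt$p, 0.001)   # strong true vss effect
  expect_error(likelihood_ratio_test(f1, f0), "nested")
  # AIC arithmetic: chi2 >= 8 with df 2 implies AIC(full) <= AIC(null) + 4
  if (lrt$chi2 >= 8) expect_lte(f1$aic, f0$aic + 4)
})

test_that("AIC selects the generating set-size form", {
  set.seed(76)
  n_p <- 30; n_t <- 64
  gen <- function(form) {
    d <- expand.grid(participant_id = sprintf("p%02d", 1:n_p), t = 1:n_t)
    d$ss <- sample(c(1, 2, 4, 8), nrow(d), TRUE)
    d$context_present <- sample(c(TRUE, FALSE), nrow(d), TRUE)
    b <- rnorm(n_p, 0, 0.3)
    mu <- if (form == "log") 1.28 + 0.40 * log(d$ss) else 1.35 + 0.13 * d$ss
    d$rt <- mu + 0.3 * d$context_present +
      b[as.integer(factor(d$participant_id))] + rnorm(nrow(d), 0, 0.7)
    d
  }
  d_log <- gen("log"); names(d_log)[names(d_log) == "ss"] <- "mss"
  expect_equal(compare_forms_aic(d_log, "mss")$selected, "log")
  d_lin <- gen("linear"); names(d_lin)[names(d_lin) == "ss"] <- "vss"
  expect_equal(compare_forms_aic(d_lin, "vss")$selected, "linear")
})

test_that("the random-intercept logistic model matches its oracles", {
  set.seed(77)
  n_p <- 25; n_t <- 40
  d <- expand.grid(participant_id = sprintf("p%02d", 1:n_p), t = 1:n_t)
  d$vss <- sample(c(1, 2, 4, 8), nrow(d), TRUE)
  d$mss <- sample(c(1, 2, 4, 8), nrow(d), TRUE)
  b <- rnorm(n_p, 0, 0.8)
  eta <- 2 - 0.15 * d$vss - 0.12 * d$mss +
    b[as.integer(factor(d$participant_id))]
  d$correct <- runif(nrow(d)) < plogis(eta)
  own <- fit_random_intercept_logistic(d, correct ~ vss + mss)
  # direction: both set sizes depress accuracy (odds ratios < 1)
  ors <- own$odds_ratios
  expect_lt(ors$odds_ratio[ors$term == "vss"], 1)
  expect_lt(ors$odds_ratio[ors$term == "mss"], 1)
  ref <- lme4::glmer(correct ~ vss + mss + (1 | participant_id), data = d,
                     family = binomial, nAGQ = 20)
  expect_equal(own$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
  expect_equal(unname(own$coefficients$estimate), unname(lme4::fixef(ref)),
               tolerance = 1e-3)

  # zero participant variance collapses exactly onto plain logistic
  # regression; the freely estimated SD on such data stays small
  d$acc0 <- runif(nrow(d)) < plogis(2 - 0.15 * d$vss - 0.12 * d$mss)
  glm0 <- stats::glm(acc0 ~ vss + mss, data = d, family = binomial)
  own_fixed <- fit_random_intercept_logistic(d, acc0 ~ vss + mss,
                                             fix_sigma_b = 1e-6)
  expect_equal(unname(own_fixed$coefficients$estimate), unname(coef(glm0)),
               tolerance = 1e-4)
  own_free <- fit_random_intercept_logistic(d, acc0 ~ vss + mss)
  expect_lt(own_free$random_intercept_sd, 0.2)

  # complete separation is an error
  d$sep <- d$vss > 2
  expect_error(fit_random_intercept_logistic(d, sep ~ vss), "separation")
})
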