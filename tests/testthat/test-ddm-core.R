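# Wiener diffusion core: closed forms, density, simulator, likelihood, fit.

test_that("choice probability matches the closed form and its symmetries", {
  expect_equal(choice_probability(ddm_params(0, 1)), 0.5)
  expect_equal(choice_probability(ddm_params(1, 1)), 1 / (1 + exp(-2)))
  # reflection: P(upper; -mu) = 1 - P(upper; mu)
  expect_equal(choice_probability(ddm_params(-1, 1)),
               1 - choice_probability(ddm_params(1, 1)))
  # simulation cross-check within 3 binomial SEs
  p <- ddm_params(1, 1, lambda = 0)
  s <- simulate_ddm(p, 2e4, dt = 0.001, seed = 5)
  phat <- mean(s$upper, na.rm = TRUE)
  se <- sqrt(choice_probability(p) * (1 - choice_probability(p)) / 2e4)
  expect_lt(abs(phat - choice_probability(p)), 3 * se)
})

test_that("mean decision time matches the closed form, its limits and monotonicity", {
  expect_equal(mean_decision_time(ddm_params(0, 1)), 1.0)
  expect_equal(mean_decision_time(ddm_params(1, 1)), tanh(1))
  expect_lt(mean_decision_time(ddm_params(1, 1e-4)), 1e-3)  # B -> 0+
  # continuous at mu -> 0
  expect_equal(mean_decision_time(ddm_params(1e-9, 1.3)),
               mean_decision_time(ddm_params(0, 1.3)), tolerance = 1e-6)
  # increasing in B at fixed mu > 0; decreasing in mu at fixed B
  mdt_B <- vapply(c(0.5, 1, 1.5, 2), function(B)
    mean_decision_time(ddm_params(1, B)), numeric(1))
  expect_true(all(diff(mdt_B) > 0))
  mdt_mu <- vapply(c(0.5, 1, 1.5, 2), function(mu)
    mean_decision_time(ddm_params(mu, 1)), numeric(1))
  expect_true(all(diff(mdt_mu) < 0))
})

test_that("the FPT density is zero before t0, integrates to the choice probability, and reflects", {
  p <- ddm_params(0.5, 1, t0 = 0.3, lambda = 0)
  expect_equal(wfpt_density(0.3, p, upper = TRUE), 0)
  expect_equal(wfpt_density(0.1, p, upper = TRUE), 0)
  g <- seq(0, 30, by = 5e-4)   # well past the deadline: capture the tail
  for (upper in c(TRUE, FALSE)) {
    dens <- wfpt_density(g, p, upper)
    quad <- (sum(dens) - (dens[1] + dens[length(dens)]) / 2) * 5e-4  # trapezoid
    target <- if (upper) choice_probability(p) else 1 - choice_probability(p)
    expect_lt(abs(quad - target), 1e-4)
  }
  # reflection symmetry to 1e-10
  ts <- c(0.4, 0.8, 1.5, 3, 6)
  d_up <- wfpt_density(ts, ddm_params(0.7, 1.1, 0.2, lambda = 0), TRUE)
  d_lo <- wfpt_density(ts, ddm_params(-0.7, 1.1, 0.2, lambda = 0), FALSE)
  expect_equal(d_up, d_lo, tolerance = 1e-10)
  expect_error(wfpt_density(NaN, p), "finite")
})

test_that("upper and lower densities conserve total probability", {
  for (par in list(c(0.5, 1), c(2, 0.6), c(-1, 2.5))) {
    p <- ddm_params(par[1], par[2], t0 = 0.2, lambda = 0, t_max = 7)
    g <- seq(0, 60, by = 1e-3)   # integrate far beyond the deadline
    tot <- sum(wfpt_density(g, p, TRUE) + wfpt_density(g, p, FALSE)) * 1e-3
    expect_lt(abs(tot - 1), 1e-3)
  }
})

test_that("the simulator is seed-deterministic and matches the analytic mean RT", {
  p <- ddm_params(1, 1, t0 = 0.3, lambda = 0)
  s1 <- simulate_ddm(p, 500, dt = 0.002, seed = 7)
  s2 <- simulate_ddm(p, 500, dt = 0.002, seed = 7)
  expect_identical(s1, s2)
  s <- simulate_ddm(p, 2e4, dt = 0.001, seed = 8)
  rts <- s$rt[!is.na(s$rt)]
  # symmetric boundaries: conditional mean decision times at both boundaries
  # equal the unconditional mean
  se <- sd(rts) / sqrt(length(rts))
  expect_lt(abs(mean(rts) - (0.3 + mean_decision_time(p))), 3 * se)
  expect_error(simulate_ddm(p, 10, dt = 0), "positive")
})

test_that("non-responses appear when the deadline truncates slow parameter regimes", {
  p <- ddm_params(0, 2.5, t0 = 0.3, lambda = 0)  # mean DT 6.25 s vs 7 s cap
  s <- simulate_ddm(p, 2000, dt = 0.002, seed = 9)
  expect_gt(mean(is.na(s$rt)), 0.2)
  expect_true(all(s$rt[!is.na(s$rt)] <= 7))
})

test_that("the robust likelihood matches its definition and the floor rescues impossible trials", {
  p0 <- ddm_params(1, 1, t0 = 0.3, lambda = 0)
  # single trial: value is -log(density) at that point
  d1 <- data.frame(upper = TRUE, rt = 0.9)
  expect_equal(robust_neg_log_likelihood(p0, d1),
               -log(wfpt_density(0.9, p0, TRUE)))
  # an rt below t0 has zero density: +Inf with lambda = 0 (warned), finite with the floor
  dd <- data.frame(upper = c(TRUE, TRUE), rt = c(0.9, 0.1))
  expect_warning(v0 <- robust_neg_log_likelihood(p0, dd), "Inf")
  expect_identical(v0, Inf)
  p2 <- ddm_params(1, 1, t0 = 0.3, lambda = 0.02)
  expect_true(is.finite(robust_neg_log_likelihood(p2, dd)))
  expect_lte(robust_neg_log_likelihood(p2, dd), v0)
  expect_error(robust_neg_log_likelihood(p2, data.frame(upper = TRUE, rt = 9)),
               "t_max")
})

test_that("the true parameters beat a drift-perturbed copy on simulated data", {
  truth <- ddm_params(1, 1.2, t0 = 0.3, lambda = 0.02)
  shifted <- ddm_params(1.5, 1.2, t0 = 0.3, lambda = 0.02)
  wins <- vapply(1:30, function(i) {
    s <- simulate_ddm(truth, 500, dt = 0.002, seed = 100 + i)
    s <- s[!is.na(s$rt), ]
    robust_neg_log_likelihood(truth, s) < robust_neg_log_likelihood(shifted, s)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("fitting is seed-deterministic and recovers a symmetric process", {
  truth <- ddm_params(0, 1, t0 = 0.25, lambda = 0.02)
  s <- simulate_ddm(truth, 2000, dt = 0.002, seed = 21)
  s <- s[!is.na(s$rt), ]
  f1 <- fit_ddm(s, seed = 3, max_gen = 150)
  f2 <- fit_ddm(s, seed = 3, max_gen = 150)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_lt(abs(f1$params$mu), 0.1)
  # error paths
  expect_error(fit_ddm(data.frame(upper = TRUE, rt = 0.5), seed = 1),
               "more trials")
  expect_error(fit_ddm(data.frame(upper = rep(TRUE, 60), rt = rep(0.5, 60)),
                       seed = 1), "identical")
  expect_warning(fit_ddm(data.frame(upper = rep(c(TRUE, FALSE), 10),
                                    rt = runif(20, 0.4, 2)),
                         seed = 1, max_gen = 5), "50 trials")
})
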