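# Three-parameter Wiener drift-diffusion model: analytic first-passage-time
# densities, closed-form summaries, trajectory simulation, the robust
# (contaminant-mixture) likelihood, and differential-evolution fitting.

#' Drift-diffusion model parameters
#'
#' The process starts at 0 between absorbing boundaries at `+B` ("present"
#' response) and `-B` ("absent"), accumulating evidence with drift `mu` and
#' diffusion coefficient `sigma`. The observed RT is the boundary-crossing
#' time plus a non-decision time `t0`; paths that have not been absorbed by
#' `t_max` are non-responses. With probability `lambda` a trial is a
#' contaminant drawn uniformly on `(t0, t_max)` with a fair-coin response,
#' which floors the likelihood against outlier RTs.
#'
#' @param mu drift rate, evidence units per second.
#' @param B boundary, evidence units (positive; boundaries at `+B`/`-B`).
#' @param t0 non-decision time, seconds (`0 <= t0 < t_max`).
#' @param sigma diffusion coefficient, evidence units per sqrt-second
#'   (fixed at 1 by convention; it only sets the evidence scale).
#' @param lambda contaminant mixture weight in `[0, 1)`.
#' @param t_max response deadline, seconds.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(mu, B, t0 = 0, sigma = 1, lambda = 0.02, t_max = 7.0) {
  stopifnot(is.finite(mu), is.finite(B), is.finite(t0))
  if (B <= 0) stopf("boundary B must be positive")
  if (sigma <= 0) stopf("sigma must be positive")
  if (lambda < 0 || lambda >= 1) stopf("lambda must lie in [0, 1)")
  if (t0 < 0 || t0 >= t_max) stopf("t0 must lie in [0, t_max)")
  structure(list(mu = mu, B = B, t0 = t0, sigma = sigma,
                 lambda = lambda, t_max = t_max),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM parameters: mu = %.4g, B = %.4g, t0 = %.4g s (sigma = %g, lambda = %g, t_max = %g s)\n",
    x$mu, x$B, x$t0, x$sigma, x$lambda, x$t_max))
  invisible(x)
}

#' Probability of absorption at the upper boundary
#'
#' Closed form `1 / (1 + exp(-2 mu B / sigma^2))` for a symmetric-start
#' Wiener process.
#'
#' @param params a [ddm_params()] object.
#' @return probability in `[0, 1]`.
#' @export
choice_probability <- function(params) {
  1 / (1 + exp(-2 * params$mu * params$B / params$sigma^2))
}

#' Mean decision time (excluding non-decision time)
#'
#' Closed form `(B/mu) * tanh(mu B / sigma^2)`, continuous at `mu = 0` where
#' it equals `B^2 / sigma^2`.
#'
#' @param params a [ddm_params()] object.
#' @return mean boundary-crossing time in seconds.
#' @export
mean_decision_time <- function(params) {
  mu <- params$mu; B <- params$B; s2 <- params$sigma^2
  if (abs(mu) < 1e-12) return(B^2 / s2)
  (B / mu) * tanh(mu * B / s2)
}

#' Wiener first-passage-time density
#'
#' Defective density of the RT at the chosen boundary, i.e. the density of
#' the boundary-crossing time shifted by the non-decision time `t0`. The
#' density at the upper boundary integrates to [choice_probability()]; zero
#' for `t <= t0`. Small-time and large-time series expansions are switched
#' at the accuracy-matched crossover and truncated for ~1e-12 absolute error.
#'
#' @param t vector of times in seconds (`t >= 0`).
#' @param params a [ddm_params()] object.
#' @param upper evaluate the density at the upper (`TRUE`) or lower boundary.
#' @return density values, per second.
#' @export
wfpt_density <- function(t, params, upper = TRUE) {
  if (any(!is.finite(t))) stopf("non-finite t passed to wfpt_density")
  if (any(t < 0)) stopf("t must be non-negative")
  .wfpt_cpp(t, params$mu, params$B, params$t0, params$sigma, upper)
}

#' Simulate drift-diffusion trials
#'
#' Euler--Maruyama simulation with increments
#' `mu * dt + sigma * sqrt(dt) * N(0, 1)`. Absorbed paths return the boundary
#' reached and `t0 +` crossing time; paths still unabsorbed at the deadline
#' return a non-response (`NA` in both columns). With probability `lambda` a
#' trial is replaced by a contaminant (uniform RT, fair-coin boundary).
#'
#' @param params a [ddm_params()] object.
#' @param n number of trials.
#' @param dt integration step in seconds (default 0.001, validation grade;
#'   0.005 is adequate for bulk experiment synthesis).
#' @param seed optional integer seed; when given, the global RNG state is
#'   left untouched.
#' @return data frame with columns `upper` (logical, `NA` = non-response)
#'   and `rt` (seconds, `NA` = non-response).
#' @export
simulate_ddm <- function(params, n, dt = 0.001, seed = NULL) {
  stopifnot(n >= 1)
  if (dt <= 0) stopf("dt must be positive")
  m <- with_seed(seed, .sim_ddm_cpp(rep(params$mu, n), rep(params$B, n),
                                    rep(params$t0, n), params$sigma,
                                    params$lambda, params$t_max, dt))
  data.frame(upper = as.logical(m[, 1]), rt = m[, 2])
}

#' Robust negative log-likelihood of choice-RT data
#'
#' Per-trial likelihood `(1 - lambda) * f(rt) + lambda / (2 (t_max - t0))`,
#' where `f` is the defective first-passage density at the response boundary.
#' The uniform contaminant floor keeps the likelihood finite for RTs the
#' diffusion process cannot produce (e.g. `rt < t0`). With `lambda = 0` such
#' trials make the value `+Inf` (with a warning).
#'
#' @param params a [ddm_params()] object.
#' @param data data frame with columns `upper` (logical) and `rt` (seconds in
#'   `(0, t_max]`); non-response rows are not allowed here.
#' @return negative log-likelihood (scalar).
#' @export
robust_neg_log_likelihood <- function(params, data) {
  if (any(is.na(data$upper)) || any(is.na(data$rt))) {
    stopf("non-response rows must be removed before computing the likelihood")
  }
  if (any(data$rt <= 0 | data$rt > params$t_max)) {
    stopf("all rt must lie in (0, t_max]")
  }
  n <- nrow(data)
  val <- .robust_nll_cpp(data$rt, data$upper,
                         rep(params$mu, n), rep(params$B, n), rep(params$t0, n),
                         params$sigma, params$lambda, params$t_max)
  if (!is.finite(val) && params$lambda == 0) {
    warnf("zero-density trial with lambda = 0; returning +Inf")
  }
  val
}

# Differential evolution (rand/1/bin) minimiser over box constraints.
# F is dithered per generation on [0.5, 1); CR = 0.7; convergence when the
# population's objective spread falls below tol (relative), or at max_gen.
de_optimize <- function(fn, lower, upper, seed = NULL,
                        pop_per_par = 15, cr = 0.7, tol = 1e-6,
                        max_gen = 300) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  np <- max(pop_per_par * d, 20)
  with_seed(seed, {
    pop <- matrix(stats::runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                  nrow = np)
    fvals <- apply(pop, 1, fn)
    n_eval <- np
    converged <- FALSE
    for (gen in seq_len(max_gen)) {
      Fw <- stats::runif(1, 0.5, 1)
      for (i in seq_len(np)) {
        idx <- sample(seq_len(np)[-i], 3)
        trial <- pop[idx[1], ] + Fw * (pop[idx[2], ] - pop[idx[3], ])
        cross <- stats::runif(d) < cr
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, trial, pop[i, ])
        # reflect out-of-bounds components back into the box
        below <- trial < lower; trial[below] <- pmin(2 * lower[below] - trial[below], upper[below])
        above <- trial > upper; trial[above] <- pmax(2 * upper[above] - trial[above], lower[above])
        trial <- pmin(pmax(trial, lower), upper)
        fv <- fn(trial)
        n_eval <- n_eval + 1
        if (fv <= fvals[i]) {
          pop[i, ] <- trial
          fvals[i] <- fv
        }
      }
      spread <- max(fvals) - min(fvals)
      if (is.finite(spread) && spread <= tol * (abs(mean(fvals)) + tol)) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(fvals)
    list(par = pop[best, ], value = fvals[best],
         n_evaluations = n_eval, converged = converged)
  })
}

#' Fit a drift-diffusion model by differential evolution
#'
#' Minimises [robust_neg_log_likelihood()] over `(mu, B, t0)` (and optionally
#' `lambda`) with a seeded rand/1/bin differential-evolution optimiser
#' (population of 15 per free parameter, CR = 0.7, F dithered on `[0.5, 1)`,
#' relative tolerance 1e-6).
#'
#' @param data data frame with columns `upper` and `rt` (answered trials
#'   only).
#' @param bounds named list of `c(lower, upper)` intervals for `mu`, `B`,
#'   `t0` and (if `fit_lambda`) `lambda`.
#' @param seed integer seed for the optimiser.
#' @param lambda contaminant weight when not fitted (default 0.02).
#' @param fit_lambda also fit the contaminant weight (default `FALSE`).
#' @param sigma fixed diffusion coefficient (default 1).
#' @param t_max response deadline in seconds (default 7).
#' @param max_gen generation cap for the optimiser.
#' @return an object of class `ddm_fit`: `params`, `neg_log_likelihood`,
#'   `n_evaluations`, `converged`, `seed`, `bounds`.
#' @export
fit_ddm <- function(data,
                    bounds = list(mu = c(-5, 5), B = c(0.2, 4), t0 = c(0, 1)),
                    seed = 1, lambda = 0.02, fit_lambda = FALSE,
                    sigma = 1, t_max = 7.0, max_gen = 300) {
  data <- data[!is.na(data$upper) & !is.na(data$rt), , drop = FALSE]
  free <- c("mu", "B", "t0", if (fit_lambda) "lambda")
  if (!all(free %in% names(bounds))) {
    stopf("bounds must be given for: %s", paste(free, collapse = ", "))
  }
  if (nrow(data) <= length(free)) {
    stopf("need more trials (%d) than free parameters (%d)", nrow(data), length(free))
  }
  if (length(unique(data$rt)) == 1 && length(unique(data$upper)) == 1) {
    stopf("all trials are identical; the likelihood surface is degenerate")
  }
  if (nrow(data) < 50) warnf("fewer than 50 trials; estimates will be unstable")
  lower <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  upper_b <- vapply(free, function(p) bounds[[p]][2], numeric(1))
  obj <- function(par) {
    names(par) <- free
    lam <- if (fit_lambda) par[["lambda"]] else lambda
    .robust_nll_cpp(data$rt, data$upper,
                    rep(par[["mu"]], nrow(data)), rep(par[["B"]], nrow(data)),
                    rep(par[["t0"]], nrow(data)), sigma, lam, t_max)
  }
  res <- de_optimize(obj, lower, upper_b, seed = seed, max_gen = max_gen)
  par <- res$par
  names(par) <- free
  params <- ddm_params(mu = par[["mu"]], B = par[["B"]], t0 = par[["t0"]],
                       sigma = sigma,
                       lambda = if (fit_lambda) par[["lambda"]] else lambda,
                       t_max = t_max)
  structure(list(params = params, neg_log_likelihood = res$value,
                 n_evaluations = res$n_evaluations, converged = res$converged,
                 seed = seed, bounds = bounds),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("DDM fit (NLL = %.3f, %s after %d evaluations, seed %d)\n",
              x$neg_log_likelihood,
              if (x$converged) "converged" else "generation cap reached",
              x$n_evaluations, x$seed))
  print(x$params)
  invisible(x)
}

#' Serialise a DDM fit to JSON
#'
#' @param fit a `ddm_fit` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ddm_fit <- function(fit, path) {
  jsonlite::write_json(
    list(params = unclass(fit$params),
         neg_log_likelihood = fit$neg_log_likelihood,
         n_evaluations = fit$n_evaluations,
         converged = fit$converged, seed = fit$seed, bounds = fit$bounds),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
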