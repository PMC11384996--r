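# Set-size statistics: per-participant linear/logarithmic RT regressions,
# their aggregation, maximum-likelihood random-intercept mixed models with
# likelihood-ratio tests and AIC form comparison, and a random-intercept
# logistic model for accuracy.
#
# The Gaussian random-intercept model is fitted by profiling: for a given
# variance ratio lambda = var_b / var_e the GLS solution and the profiled
# ML deviance are closed-form (groupwise Woodbury), leaving a 1-D bounded
# search over log(lambda).

#' Per-participant RT-by-set-size curve fits
#'
#' For each participant and context condition, mean RT is computed at each
#' level of the chosen set-size axis (with the other axis restricted to
#' `fixed_other`), then ordinary least squares of mean RT on set size
#' (linear form) and on `ln(set size)` (log form). Both forms are returned
#' with R-squared and Gaussian AIC.
#'
#' @param trials trials already filtered to correct, answered,
#'   target-present rows.
#' @param axis `"vss"` or `"mss"`.
#' @param fixed_other level at which the other set-size axis is held
#'   (default 4).
#' @return data frame of class `curve_fits`: one row per participant x
#'   context x form with `slope`, `intercept`, `r_squared`, `aic`,
#'   `n_points`. Participants with fewer than 2 distinct levels are skipped
#'   (recorded in the `skipped` attribute).
#' @export
participant_setsize_curves <- function(trials, axis = c("vss", "mss"),
                                       fixed_other = 4) {
  axis <- match.arg(axis)
  other <- if (axis == "vss") "mss" else "vss"
  df <- as.data.frame(trials)
  df <- df[df[[other]] == fixed_other & !is.na(df$rt), , drop = FALSE]
  out <- list()
  skipped <- character(0)
  for (pid in unique(df$participant_id)) {
    for (ctx in c(FALSE, TRUE)) {
      sub <- df[df$participant_id == pid & df$context_present == ctx, ]
      if (nrow(sub) == 0) next
      means <- tapply(sub$rt, sub[[axis]], mean)
      x <- as.numeric(names(means))
      y <- as.numeric(means)
      if (length(x) < 2) {
        skipped <- c(skipped, sprintf("%s/context=%s", pid, ctx))
        next
      }
      for (form in c("linear", "log")) {
        xf <- if (form == "log") log(x) else x
        fit <- stats::lm.fit(cbind(1, xf), y)
        rss <- sum(fit$residuals^2)
        tss <- sum((y - mean(y))^2)
        out[[length(out) + 1]] <- data.frame(
          participant_id = pid, axis = axis, context = ctx, form = form,
          slope = fit$coefficients[2], intercept = fit$coefficients[1],
          r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
          aic = gaussian_aic(max(rss, 1e-300), length(y), 3),
          n_points = length(y)
        )
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(participant_id = character(0), axis = character(0),
                      context = logical(0), form = character(0),
                      slope = numeric(0), intercept = numeric(0),
                      r_squared = numeric(0), aic = numeric(0),
                      n_points = integer(0))
  } else {
    res <- do.call(rbind, out)
  }
  rownames(res) <- NULL
  structure(res, class = c("curve_fits", "data.frame"), skipped = skipped)
}

#' Aggregate per-participant curve fits
#'
#' Mean and standard error (SD / sqrt(n)) of slope, intercept and R-squared
#' per (axis, context, form) cell, mirroring the "mean +/- SEM of the
#' individual fits" reporting convention.
#'
#' @param fits output of [participant_setsize_curves()].
#' @return data frame with one row per cell.
#' @export
aggregate_curves <- function(fits) {
  df <- as.data.frame(fits)
  key <- interaction(df$axis, df$context, df$form, drop = TRUE)
  rows <- lapply(levels(key), function(kl) {
    sub <- df[key == kl, ]
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    data.frame(axis = sub$axis[1], context = sub$context[1],
               form = sub$form[1], n = nrow(sub),
               slope_mean = mean(sub$slope), slope_sem = sem(sub$slope),
               intercept_mean = mean(sub$intercept),
               intercept_sem = sem(sub$intercept),
               r_squared_mean = mean(sub$r_squared),
               r_squared_sem = sem(sub$r_squared))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Build the fixed-effects design matrix from a one-sided/two-sided formula on
# the trial data; errors on rank deficiency, naming an aliased column.
build_design_matrix <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("singular fixed-effects design; aliased term(s): %s",
          paste(aliased, collapse = ", "))
  }
  list(y = y, X = X)
}

# Profiled ML deviance machinery for the Gaussian random-intercept model.
# Given lambda, V_i = I + lambda * J within group i; V_i^{-1} has the
# Woodbury form I - (lambda / (1 + lambda n_i)) J, and log|V_i| =
# log(1 + lambda n_i).
profiled_lmm <- function(y, X, group, lambda) {
  gsize <- tabulate(group)
  shrink <- lambda / (1 + lambda * gsize)       # per group
  Xg <- rowsum(X, group)                        # group sums of columns
  yg <- rowsum(y, group)[, 1]
  XtVX <- crossprod(X) - crossprod(Xg * sqrt(shrink))
  XtVy <- crossprod(X, y) - crossprod(Xg * sqrt(shrink), yg * sqrt(shrink))
  beta <- solve(XtVX, XtVy)[, 1]
  r <- y - X %*% beta
  rg <- rowsum(r, group)[, 1]
  rss <- sum(r^2) - sum(shrink * rg^2)
  n <- length(y)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) - sum(log1p(lambda * gsize)) / 2
  list(beta = beta, sigma2 = sigma2, ll = ll, XtVX = XtVX)
}

#' Random-intercept linear mixed model (maximum likelihood)
#'
#' Fits `response ~ fixed effects + (1 | group)` by full maximum likelihood
#' (not REML), profiling the fixed effects and residual variance and
#' optimising the between/within variance ratio by one-dimensional bounded
#' search. Wald (normal) 95% confidence intervals are reported for the fixed
#' effects; `AIC = -2 logLik + 2 k` counts all fixed effects plus the two
#' variance parameters.
#'
#' @param data trial-level data frame.
#' @param formula fixed-effects formula, e.g. `rt ~ vss * context_present`.
#' @param group name of the grouping column (default `"participant_id"`).
#' @return an object of class `lmm_fit`: `fixed_effects` (data frame with
#'   estimates, SEs, Wald 95% CIs, z and p), `random_intercept_sd`,
#'   `residual_sd`, `icc`, `log_likelihood`, `aic`, `n_obs`, `n_groups`.
#' @export
fit_random_intercept_lmm <- function(data, formula,
                                     group = "participant_id") {
  df <- as.data.frame(data)
  dm <- build_design_matrix(formula, df)
  g <- as.integer(factor(df[[group]]))
  if (length(unique(g)) < 2) stopf("need at least 2 groups")
  dev <- function(theta) -profiled_lmm(dm$y, dm$X, g, exp(theta))$ll
  opt <- stats::optimize(dev, lower = log(1e-8), upper = log(1e4))
  # compare against the boundary lambda -> 0 (no participant variance)
  ll0 <- profiled_lmm(dm$y, dm$X, g, 1e-12)$ll
  if (ll0 > -opt$objective) {
    lambda <- 1e-12
  } else {
    lambda <- exp(opt$minimum)
  }
  fit <- profiled_lmm(dm$y, dm$X, g, lambda)
  vcov_beta <- fit$sigma2 * solve(fit$XtVX)
  se <- sqrt(diag(vcov_beta))
  z <- fit$beta / se
  fx <- data.frame(term = colnames(dm$X), estimate = fit$beta, se = se,
                   ci_lower = fit$beta - 1.96 * se,
                   ci_upper = fit$beta + 1.96 * se,
                   z = z, p = 2 * stats::pnorm(-abs(z)))
  rownames(fx) <- NULL
  k <- ncol(dm$X) + 2
  icc <- lambda / (1 + lambda)
  structure(list(fixed_effects = fx,
                 random_intercept_sd = sqrt(fit$sigma2 * lambda),
                 residual_sd = sqrt(fit$sigma2),
                 icc = icc,
                 log_likelihood = fit$ll,
                 aic = -2 * fit$ll + 2 * k,
                 n_obs = length(dm$y), n_groups = length(unique(g)),
                 n_fixed = ncol(dm$X), formula = formula, group = group),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (ML): %s, %d obs / %d groups\n",
              deparse(x$formula), x$n_obs, x$n_groups))
  cat(sprintf("  logLik = %.2f, AIC = %.1f, ICC = %.3f (sd_b = %.3f, sd_e = %.3f)\n",
              x$log_likelihood, x$aic, x$icc,
              x$random_intercept_sd, x$residual_sd))
  print(x$fixed_effects, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' `chi2 = 2 (logLik_full - logLik_null)` on the difference in fixed-effect
#' counts; both models must be ML fits to the same observations.
#'
#' @param null the reduced-model [fit_random_intercept_lmm()] fit.
#' @param full the larger-model fit.
#' @return list: `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(null, full) {
  if (null$n_obs != full$n_obs || null$n_groups != full$n_groups) {
    stopf("models were fitted to different data")
  }
  df <- full$n_fixed - null$n_fixed
  if (df < 0) stopf("null model has more parameters than the full model; not nested")
  chi2 <- max(0, 2 * (full$log_likelihood - null$log_likelihood))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Compare linear and logarithmic set-size forms by AIC
#'
#' Fits the full random-intercept models `rt ~ ss * context + (1 | group)`
#' with the set-size term entered untransformed and log-transformed, and
#' reports both AICs and the selected (lower-AIC) form.
#'
#' @param trials filtered trial data.
#' @param axis `"vss"` or `"mss"`.
#' @param group grouping column name.
#' @return list: `aic_linear`, `aic_log`, `selected` (`"linear"` or
#'   `"log"`), `fit_linear`, `fit_log`.
#' @export
compare_forms_aic <- function(trials, axis = c("vss", "mss"),
                              group = "participant_id") {
  axis <- match.arg(axis)
  df <- as.data.frame(trials)
  df$ss_lin <- df[[axis]]
  df$ss_log <- log(df[[axis]])
  fit_lin <- fit_random_intercept_lmm(df, rt ~ ss_lin * context_present,
                                      group = group)
  fit_log <- fit_random_intercept_lmm(df, rt ~ ss_log * context_present,
                                      group = group)
  list(aic_linear = fit_lin$aic, aic_log = fit_log$aic,
       selected = if (fit_lin$aic <= fit_log$aic) "linear" else "log",
       fit_linear = fit_lin, fit_log = fit_log)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-x^2)).
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = sqrt(pi) * e$vectors[1, idx]^2)
}

#' Random-intercept logistic regression (adaptive Gauss-Hermite)
#'
#' Fits a logistic mixed model with a per-group Gaussian random intercept.
#' The marginal likelihood is integrated by adaptive Gauss-Hermite
#' quadrature (per-group mode and curvature found by Newton steps, default
#' 20 nodes) and maximised over the fixed effects and the random-intercept
#' SD. Reports odds ratios with Wald 95% CIs.
#'
#' @param data trial-level data frame; the response must be binary (logical
#'   or 0/1).
#' @param formula fixed-effects formula, e.g.
#'   `correct ~ vss + mss + context_present`.
#' @param group grouping column name.
#' @param n_quad number of quadrature nodes (default 20).
#' @param fix_sigma_b optionally fix the random-intercept SD instead of
#'   estimating it; at values near zero the model collapses exactly onto
#'   ordinary logistic regression.
#' @return an object of class `glmm_fit`: `coefficients` (log-odds scale
#'   with SE), `odds_ratios` (with CIs), `random_intercept_sd`,
#'   `log_likelihood`, `aic`, `n_obs`, `n_groups`.
#' @export
fit_random_intercept_logistic <- function(data, formula,
                                          group = "participant_id",
                                          n_quad = 20, fix_sigma_b = NULL) {
  df <- as.data.frame(data)
  dm <- build_design_matrix(formula, df)
  y <- as.numeric(dm$y)
  if (!all(y %in% c(0, 1))) stopf("response must be binary")
  X <- dm$X
  g <- as.integer(factor(df[[group]]))
  ng <- max(g)

  # guard against complete separation using the fixed-effects-only fit
  glm0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (any(abs(glm0$coefficients) > 15) ||
      any(glm0$fitted.values > 1 - 1e-10) || any(glm0$fitted.values < 1e-10)) {
    stopf("complete (or quasi-complete) separation in the fixed effects")
  }

  gh <- gauss_hermite(n_quad)
  rows_by_group <- split(seq_along(y), g)

  neg_marg_ll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    sigma_b <- if (is.null(fix_sigma_b)) exp(par[length(par)]) else fix_sigma_b
    eta0 <- drop(X %*% beta)
    ll <- 0
    for (rows in rows_by_group) {
      yi <- y[rows]; ei <- eta0[rows]
      h <- function(b) {
        # stable Bernoulli log-likelihood: log p(y|eta) = -log(1+exp((1-2y) eta))
        a <- (1 - 2 * yi) * (ei + b)
        sum(-(pmax(a, 0) + log1p(exp(-abs(a))))) - b^2 / (2 * sigma_b^2) -
          log(sigma_b) - 0.5 * log(2 * pi)
      }
      # Newton search for the mode of the integrand
      b <- 0
      for (it in 1:25) {
        p <- stats::plogis(ei + b)
        g1 <- sum(yi - p) - b / sigma_b^2
        g2 <- -sum(p * (1 - p)) - 1 / sigma_b^2
        step <- g1 / g2
        b <- b - step
        if (abs(step) < 1e-9) break
      }
      p <- stats::plogis(ei + b)
      tau <- 1 / sqrt(sum(p * (1 - p)) + 1 / sigma_b^2)
      nodes <- b + sqrt(2) * tau * gh$nodes
      hv <- vapply(nodes, h, numeric(1))
      lt <- log(gh$weights) + hv + gh$nodes^2   # log-sum-exp for stability
      m <- max(lt)
      ll <- ll + m + log(sum(exp(lt - m))) + log(sqrt(2) * tau)
    }
    -ll
  }

  est_sigma <- is.null(fix_sigma_b)
  start <- c(glm0$coefficients, if (est_sigma) log(0.5))
  opt <- stats::optim(start, neg_marg_ll, method = "L-BFGS-B",
                      lower = c(rep(-20, ncol(X)), if (est_sigma) log(1e-4)),
                      upper = c(rep(20, ncol(X)), if (est_sigma) log(10)),
                      hessian = TRUE)
  beta <- opt$par[seq_len(ncol(X))]
  sigma_b <- if (est_sigma) exp(opt$par[length(opt$par)]) else fix_sigma_b
  H <- opt$hessian[seq_len(ncol(X)), seq_len(ncol(X)), drop = FALSE]
  se <- sqrt(diag(solve(H)))
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      z = beta / se, p = 2 * stats::pnorm(-abs(beta / se)))
  ors <- data.frame(term = colnames(X), odds_ratio = exp(beta),
                    ci_lower = exp(beta - 1.96 * se),
                    ci_upper = exp(beta + 1.96 * se))
  rownames(coefs) <- rownames(ors) <- NULL
  ll <- -opt$value
  k <- ncol(X) + as.integer(est_sigma)
  structure(list(coefficients = coefs, odds_ratios = ors,
                 random_intercept_sd = sigma_b,
                 log_likelihood = ll, aic = -2 * ll + 2 * k,
                 n_obs = length(y), n_groups = ng,
                 formula = formula, n_quad = n_quad),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept logistic model (AGQ %d nodes): %s\n",
              x$n_quad, deparse(x$formula)))
  cat(sprintf("  logLik = %.2f, AIC = %.1f, sd_b = %.3f\n",
              x$log_likelihood, x$aic, x$random_intercept_sd))
  print(x$odds_ratios, digits = 3)
  invisible(x)
}
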