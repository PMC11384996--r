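# Condition-to-parameter mapping for hybrid search: drift depends on the
# memory set size and scene context, the boundary on the visual set size,
# and the non-decision time is constant (optionally different for
# target-absent trials in the extended model).

#' Hybrid-search DDM specification
#'
#' Maps an experimental condition (memory set size MSS, visual set size VSS,
#' context, target presence) onto [ddm_params()]:
#' \itemize{
#'   \item drift `= mu0 / (1 + gamma * ln(MSS)) + delta * context` under the
#'     default `inverse_log_mss` form, or `mu0 / (1 + gamma * (MSS - 1)) +
#'     delta * context` under `inverse_mss`;
#'   \item boundary `= a0 + a1 * VSS` (target present), or
#'     `a0_ta + a1_ta * VSS` when the extended target-absent parameters are
#'     set;
#'   \item non-decision time `t0` constant (or `t0_ta` for target absent in
#'     the extended model).
#' }
#' The drift is signed toward the correct boundary: positive (toward the
#' upper, "present" boundary) on target-present trials and reversed on
#' target-absent trials, so the same memory/context mechanism drives both
#' decisions.
#'
#' The defaults are the calibration used by the synthetic-experiment
#' generator; they reproduce an approximately linear mean-RT growth in VSS
#' (~0.19 s/item at MSS 4) and logarithmic growth in MSS.
#'
#' @param mu0 drift scale, evidence/s (positive).
#' @param gamma drift attenuation per log-unit of MSS (non-negative).
#' @param delta additive context offset on the drift, evidence/s (signed).
#' @param a0 boundary intercept, evidence units (positive).
#' @param a1 boundary slope per visual item (non-negative).
#' @param t0 non-decision time, seconds.
#' @param lambda contaminant weight shared across cells.
#' @param drift_form `"inverse_log_mss"` (default) or `"inverse_mss"`.
#' @param a0_ta,a1_ta,t0_ta optional target-absent boundary/non-decision
#'   parameters (extended model; `NULL` = same as target present).
#' @param sigma diffusion coefficient (default 1).
#' @param t_max response deadline, seconds.
#' @return an object of class `hybrid_ddm_spec`.
#' @export
hybrid_ddm_spec <- function(mu0 = 2.0, gamma = 0.8, delta = -0.4,
                            a0 = 0.8, a1 = 0.15, t0 = 0.35,
                            lambda = 0.02,
                            drift_form = c("inverse_log_mss", "inverse_mss"),
                            a0_ta = NULL, a1_ta = NULL, t0_ta = NULL,
                            sigma = 1, t_max = 7.0) {
  drift_form <- match.arg(drift_form)
  if (mu0 <= 0) stopf("mu0 must be positive")
  if (gamma < 0) stopf("gamma must be non-negative")
  if (a0 <= 0) stopf("a0 must be positive")
  if (a1 < 0) stopf("a1 must be non-negative")
  structure(list(mu0 = mu0, gamma = gamma, delta = delta,
                 a0 = a0, a1 = a1, t0 = t0, lambda = lambda,
                 drift_form = drift_form,
                 a0_ta = a0_ta, a1_ta = a1_ta, t0_ta = t0_ta,
                 sigma = sigma, t_max = t_max),
            class = "hybrid_ddm_spec")
}

#' @export
print.hybrid_ddm_spec <- function(x, ...) {
  cat(sprintf(
    "Hybrid DDM spec (%s): mu0 = %.3g, gamma = %.3g, delta = %.3g; a0 = %.3g, a1 = %.3g; t0 = %.3g s; lambda = %g\n",
    x$drift_form, x$mu0, x$gamma, x$delta, x$a0, x$a1, x$t0, x$lambda))
  if (!is.null(x$a0_ta)) {
    cat(sprintf("  target-absent: a0 = %.3g, a1 = %.3g, t0 = %.3g s\n",
                x$a0_ta, x$a1_ta %||% x$a1, x$t0_ta %||% x$t0))
  }
  invisible(x)
}

has_ta_params <- function(spec) {
  !is.null(spec$a0_ta) || !is.null(spec$a1_ta) || !is.null(spec$t0_ta)
}

# Vectorised mapping of conditions onto per-trial (mu, B, t0) vectors.
# Drift is signed toward the correct boundary (negative on target-absent
# trials).
map_condition_vec <- function(spec, mss, vss, context, target_present) {
  if (any(mss < 1) || any(vss < 1)) stopf("mss and vss must be >= 1")
  atten <- switch(spec$drift_form,
    inverse_log_mss = 1 + spec$gamma * log(mss),
    inverse_mss = 1 + spec$gamma * (mss - 1)
  )
  drift <- spec$mu0 / atten + spec$delta * as.numeric(context)
  drift <- drift * ifelse(target_present, 1, -1)
  if (has_ta_params(spec)) {
    a0 <- ifelse(target_present, spec$a0, spec$a0_ta %||% spec$a0)
    a1 <- ifelse(target_present, spec$a1, spec$a1_ta %||% spec$a1)
    t0 <- ifelse(target_present, spec$t0, spec$t0_ta %||% spec$t0)
  } else {
    a0 <- spec$a0; a1 <- spec$a1; t0 <- spec$t0
  }
  n <- max(length(mss), length(vss), length(context), length(target_present))
  list(mu = rep_len(drift, n), B = rep_len(a0 + a1 * vss, n),
       t0 = rep_len(t0, n))
}

#' Map a condition onto single-process DDM parameters
#'
#' @param spec a [hybrid_ddm_spec()].
#' @param mss memory set size (>= 1).
#' @param vss visual set size (>= 1).
#' @param context logical, scene context present.
#' @param target_present logical (default `TRUE`).
#' @return a [ddm_params()] object for that condition cell.
#' @export
map_condition <- function(spec, mss, vss, context, target_present = TRUE) {
  p <- map_condition_vec(spec, mss, vss, context, target_present)
  ddm_params(mu = p$mu[1], B = p$B[1], t0 = p$t0[1], sigma = spec$sigma,
             lambda = spec$lambda, t_max = spec$t_max)
}

# Joint robust NLL of answered trials under a spec. `trials` needs columns
# mss, vss, context_present, target_present, response, rt.
hybrid_nll <- function(spec, trials) {
  p <- map_condition_vec(spec, trials$mss, trials$vss,
                         trials$context_present, trials$target_present)
  .robust_nll_cpp(trials$rt, trials$response == "present",
                  p$mu, p$B, p$t0, spec$sigma, spec$lambda, spec$t_max)
}

#' Fit the hybrid condition-to-parameter mapping jointly
#'
#' Single joint robust likelihood over all answered trials, each trial
#' evaluated under the DDM parameters mapped from its condition cell; shared
#' parameters are genuinely shared across cells. Optimised by the same
#' differential-evolution scheme as [fit_ddm()]. With `extended = TRUE` the
#' target-absent boundary and non-decision parameters (`a0_ta`, `a1_ta`,
#' `t0_ta`) are also fitted, and target-absent trials should be included in
#' `trials`.
#'
#' @param trials a [trial_table()] (or data frame) of answered trials.
#'   The core fit uses all answered target-present trials -- correct and
#'   error responses alike -- so the two-boundary defective density is a
#'   proper likelihood (fitting correct-only data would bias the drift and
#'   boundary upward to explain the missing errors). The extended model
#'   additionally takes answered target-absent trials.
#' @param template a [hybrid_ddm_spec()] providing fixed values and the drift
#'   form.
#' @param free character vector of parameter names to fit; defaults to
#'   `c("mu0", "gamma", "delta", "a0", "a1", "t0")` (plus the `_ta`
#'   parameters when `extended`). An empty vector returns the template's
#'   likelihood without optimisation.
#' @param bounds named list of `c(lower, upper)` per free parameter; defaults
#'   cover the plausible range for second-scale RT data.
#' @param seed optimiser seed.
#' @param extended fit the target-absent extension (default `FALSE`).
#' @param max_gen generation cap for the optimiser.
#' @return an object of class `hybrid_ddm_fit`: `spec` (fitted),
#'   `neg_log_likelihood`, `predictions` (per-cell analytic mean RT and
#'   response probability), `n_evaluations`, `converged`, `seed`, `bounds`.
#' @export
fit_hybrid <- function(trials, template = hybrid_ddm_spec(),
                       free = NULL, bounds = NULL, seed = 1,
                       extended = FALSE, max_gen = 250) {
  trials <- as.data.frame(trials)
  trials <- trials[trials$response != "none" & !is.na(trials$rt), , drop = FALSE]
  if (!extended && any(!trials$target_present)) {
    trials <- trials[trials$target_present, , drop = FALSE]
  }
  if (nrow(trials) == 0) stopf("no answered trials to fit")
  if (is.null(free)) {
    free <- c("mu0", "gamma", "delta", "a0", "a1", "t0",
              if (extended) c("a0_ta", "a1_ta", "t0_ta"))
  }
  default_bounds <- list(
    mu0 = c(0.1, 6), gamma = c(0, 4), delta = c(-2, 2),
    a0 = c(0.1, 3), a1 = c(0, 1), t0 = c(0, 1),
    a0_ta = c(0.1, 3), a1_ta = c(0, 1), t0_ta = c(0, 1),
    lambda = c(0, 0.3)
  )
  bounds <- utils::modifyList(default_bounds, bounds %||% list())

  # warn about empty design cells
  grid <- expand.grid(mss = SET_SIZE_LEVELS, vss = SET_SIZE_LEVELS,
                      context = c(FALSE, TRUE))
  present <- interaction(trials$mss, trials$vss, trials$context_present)
  empty <- !interaction(grid$mss, grid$vss, grid$context) %in% unique(present)
  if (any(empty)) warnf("%d design cell(s) contain no trials; skipped", sum(empty))

  apply_par <- function(par) {
    sp <- unclass(template)
    sp[free] <- as.list(par)
    if (extended) {
      sp$a0_ta <- sp$a0_ta %||% template$a0
      sp$a1_ta <- sp$a1_ta %||% template$a1
      sp$t0_ta <- sp$t0_ta %||% template$t0
    }
    class(sp) <- "hybrid_ddm_spec"
    sp
  }

  if (length(free) == 0) {
    res <- list(par = numeric(0), value = hybrid_nll(template, trials),
                n_evaluations = 1, converged = TRUE)
    fitted_spec <- template
  } else {
    lower <- vapply(free, function(p) bounds[[p]][1], numeric(1))
    upper <- vapply(free, function(p) bounds[[p]][2], numeric(1))
    obj <- function(par) {
      names(par) <- free
      hybrid_nll(apply_par(par), trials)
    }
    res <- de_optimize(obj, lower, upper, seed = seed, max_gen = max_gen)
    names(res$par) <- free
    fitted_spec <- apply_par(res$par)
  }

  structure(list(spec = fitted_spec,
                 neg_log_likelihood = res$value,
                 predictions = analytic_surface(fitted_spec, trials),
                 n_evaluations = res$n_evaluations,
                 converged = res$converged, seed = seed,
                 bounds = bounds[free]),
            class = "hybrid_ddm_fit")
}

#' @export
print.hybrid_ddm_fit <- function(x, ...) {
  cat(sprintf("Hybrid DDM fit (joint NLL = %.3f, %s, seed %d)\n",
              x$neg_log_likelihood,
              if (x$converged) "converged" else "generation cap reached",
              x$seed))
  print(x$spec)
  invisible(x)
}

# Closed-form per-cell expectations (mean RT = t0 + mean decision time,
# response split from the absorption probability) over the cells present in
# the data.
analytic_surface <- function(spec, trials) {
  cells <- unique(trials[c("mss", "vss", "context_present", "target_present")])
  cells <- cells[order(cells$target_present, cells$context_present,
                       cells$mss, cells$vss), , drop = FALSE]
  rownames(cells) <- NULL
  p <- map_condition_vec(spec, cells$mss, cells$vss, cells$context_present,
                         cells$target_present)
  pu <- 1 / (1 + exp(-2 * p$mu * p$B / spec$sigma^2))
  mdt <- ifelse(abs(p$mu) < 1e-12, p$B^2 / spec$sigma^2,
                (p$B / p$mu) * tanh(p$mu * p$B / spec$sigma^2))
  cells$mean_rt <- p$t0 + mdt
  cells$p_present <- pu
  cells
}

#' Simulated per-condition RT and accuracy surface
#'
#' For each cell of the design grid, simulates `n_sims` trials from the
#' mapped DDM and reports the mean RT of correct responses, the response
#' split and the non-response rate.
#'
#' @param spec a [hybrid_ddm_spec()].
#' @param n_sims simulations per cell (default 10000).
#' @param seed integer seed.
#' @param dt integration step, seconds (default 0.005 for bulk synthesis).
#' @param set_sizes design levels for both MSS and VSS.
#' @param target_present which target conditions to simulate (default
#'   present-only, matching the core model fit).
#' @return data frame with one row per cell: `mss`, `vss`,
#'   `context_present`, `target_present`, `mean_rt_correct`, `p_present`,
#'   `p_nonresponse`, `n_correct`.
#' @export
predict_rt_surface <- function(spec, n_sims = 10000, seed = NULL, dt = 0.005,
                               set_sizes = SET_SIZE_LEVELS,
                               target_present = TRUE) {
  grid <- expand.grid(mss = set_sizes, vss = set_sizes,
                      context_present = c(FALSE, TRUE),
                      target_present = target_present)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      p <- map_condition_vec(spec, g$mss, g$vss, g$context_present,
                             g$target_present)
      m <- .sim_ddm_cpp(rep(p$mu, n_sims), rep(p$B, n_sims), rep(p$t0, n_sims),
                        spec$sigma, spec$lambda, spec$t_max, dt)
      upper <- m[, 1]; rt <- m[, 2]
      answered <- !is.na(upper)
      correct <- answered & (upper == as.numeric(g$target_present))
      data.frame(
        g,
        mean_rt_correct = if (any(correct)) mean(rt[correct]) else NA_real_,
        p_present = mean(upper[answered] == 1),
        p_nonresponse = mean(!answered),
        n_correct = sum(correct)
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
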