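#!/usr/bin/env Rscript

# Stage 6 — model validation by simulation.
#
# Simulates 10,000 trials per design cell from the fitted target-present
# mapping and checks that the model reproduces the behavioural set-size
# signatures: mean RT approximately linear in visual set size and
# logarithmic in memory set size.

library(hybridsearch)

seed <- 20260 + 6
fit <- jsonlite::read_json("results/hybrid_fit_target_present.json",
                           simplifyVector = TRUE)
spec <- do.call(hybrid_ddm_spec,
                fit$spec[c("mu0", "gamma", "delta", "a0", "a1", "t0",
                           "lambda", "drift_form")])
surf <- predict_rt_surface(spec, n_sims = 10000, seed = seed)
write.csv(surf, "results/rt_surface.csv", row.names = FALSE)

for (ctx in c(FALSE, TRUE)) {
  vs <- surf[surf$mss == 4 & surf$context_present == ctx, ]
  r2 <- summary(lm(mean_rt_correct ~ vss, vs))$r.squared
  ms <- surf[surf$vss == 4 & surf$context_present == ctx, ]
  rss_lin <- sum(resid(lm(mean_rt_correct ~ mss, ms))^2)
  rss_log <- sum(resid(lm(mean_rt_correct ~ log(mss), ms))^2)
  cat(sprintf("context %-5s: RTxVSS linear R2 = %.3f; RTxMSS log/linear RSS = %.2f (log better if < 1)\n",
              ctx, r2, rss_log / rss_lin))
}
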