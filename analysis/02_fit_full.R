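#!/usr/bin/env Rscript
# Stage 2: fit the full bifactor model and extract D.
#
# Reads the stage-1 responses, fits the 151-item / 17-factor bifactor model
# by maximum likelihood, reports the global fit indices, and writes the fit
# (parameters + indices), the per-scale ECV table and the regression-method
# D scores used as the criterion by stage 3.

library(darkcore)

map <- read_scale_map("results/scale_map.csv")
X <- read_responses("scratch/data/responses.csv", map)
spec <- model_spec(map)
cat(sprintf("Model: %d items, %d factors, df = %d\n",
            spec$p, spec$n_scales + 1L, degrees_of_freedom(spec)))

fit <- fit_bifactor(sample_covariance(X), nrow(X), spec,
                    engine_options(seed = 20260930L))
print(fit)

write_fit(fit, "results/full_fit.json")
e <- ecv(fit)
write.csv(data.frame(scale = names(e), ecv = round(unname(e), 4)),
          "results/ecv.csv", row.names = FALSE)
cat("\nECV (D saturation) by scale, descending:\n")
print(data.frame(scale = names(sort(e, decreasing = TRUE)),
                 ecv = round(sort(e, decreasing = TRUE), 3)),
      row.names = FALSE)

scores <- score_general_factor(X, fit)
write.csv(data.frame(respondent = seq_along(scores), d_score = scores),
          "scratch/data/d_scores.csv", row.names = FALSE)
cat("\nWrote results/full_fit.json, results/ecv.csv, scratch/data/d_scores.csv\n")
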