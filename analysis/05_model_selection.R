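#!/usr/bin/env Rscript
# Stage 5: LASSO selection of the optimal combined model.
#
# Step 4 of the modeling plan: one multivariable LASSO over the selected
# established risk markers plus all retained biomarkers, penalty tuned by
# minimizing the leave-one-out cross-validated MSE (82 folds). The CV curve
# (MSE vs log lambda) and the optimal coefficients are written; the curve
# reproduces the familiar path-selection figure.

suppressMessages(library(renalpanel))

SEED <- 2026
cohort <- simulate_cohort(gen_config(n_patients = 82, seed = SEED))
cfg <- run_config(m = 5, cycles = 10, seed = SEED)
built <- renalpanel:::build_analysis_data(cohort, cfg)
model_cols <- setdiff(names(built$data), c("id", "slope", "accelerated"))
imp <- impute_chained(built$data[c("slope", model_cols)], m = 5, cycles = 10,
                      seed = substream_seed(SEED, "imputation"))
d1 <- imp$datasets[[1]]

ref_fit <- select_model(d1, model_spec("established",
                                       renalpanel:::established_markers()))
full_spec <- model_spec("full", c(ref_fit$active, built$biomarkers))
full_fit <- select_model(d1, full_spec)

dir.create("results", showWarnings = FALSE)
cv <- full_fit$cv
write.csv(data.frame(lambda = cv$lambda, log_lambda = log(cv$lambda),
                     cv_mse = cv$cv_mse, cv_se = cv$cv_se),
          "results/cv_curve.csv", row.names = FALSE)
write.csv(data.frame(variable = names(full_fit$coefficients),
                     coefficient = full_fit$coefficients,
                     selected = full_fit$coefficients != 0),
          "results/optimal_model.csv", row.names = FALSE)
pdf("results/cv_curve.pdf", width = 6, height = 4.5)
plot(cv, main = "LASSO selection: combined model")
dev.off()

print(cv)
cat(sprintf("optimal model: %d of %d candidates active\n",
            length(full_fit$active), length(full_spec$predictors)))
print(full_fit)
cat("wrote results/{cv_curve.csv,optimal_model.csv,cv_curve.pdf}\n")
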