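#!/usr/bin/env Rscript
## Variance-based sensitivity ranking of the derived metrics over
## Population I: Sobol S1/ST (with bootstrap confidence), the linear R^2
## of each metric, and random-forest permutation importance (the method
## used for the non-uniform Population II, shown here on Population I for
## comparison with the Sobol ranking).

library(proarisk)

out <- "results"
pop <- read_population(file.path(out, "population1.csv"),
                       scheme = "saltelli", n = 32, second_order = TRUE,
                       seed = 1)
metrics <- read.csv(file.path(out, "metrics1.csv"))

res <- list()
for (metric in c("qNet", "APD90", "peakCa")) {
  y <- metrics[[metric]]
  sob <- sobol_indices(pop, y, n_boot = 100, seed = 1)
  ok <- !is.na(y)
  lin <- linear_r2(pop$samples[ok, ], y[ok])
  mda <- mda_importance(pop$samples[ok, ], y[ok],
                        surrogate = "rf_regressor", repeats = 5, seed = 1)
  top <- names(sort(sob$S1, decreasing = TRUE))[1:3]
  cat(sprintf("%-7s R2(linear) %.2f | top S1: %s (%.2f, %.2f, %.2f) | top MDA: %s\n",
              metric, lin$r2,
              paste(top, collapse = "/"),
              sob$S1[top[1]], sob$S1[top[2]], sob$S1[top[3]],
              names(which.max(mda$drops))))
  res[[metric]] <- list(
    sobol = list(S1 = as.list(sob$S1), ST = as.list(sob$ST),
                 S1_conf = as.list(sob$S1_conf),
                 ST_conf = as.list(sob$ST_conf),
                 n_imputed = sob$n_imputed),
    linear_r2 = lin$r2,
    mda = list(baseline = mda$baseline, drops = as.list(mda$drops)))
}
jsonlite::write_json(res, file.path(out, "gsa1.json"), auto_unbox = TRUE,
                     digits = NA)
cat("sensitivity results written to", file.path(out, "gsa1.json"), "\n")
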