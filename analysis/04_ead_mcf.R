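#!/usr/bin/env Rscript
## EAD-threshold protocol and Monte Carlo filtering.
##
## For a subsample of Population I we estimate Th_EAD,hERG (the minimal
## additional percent IKr conductance reduction that elicits an EAD) and
## then rank the nine inputs by the Kolmogorov-Smirnov distance between
## the behavioural (no EAD at a fixed perturbation) and non-behavioural
## subsets, and between qNet-defined risk tertiles.

library(proarisk)

out <- "results"
pop <- read_population(file.path(out, "population1.csv"),
                       scheme = "saltelli", n = 32, second_order = TRUE,
                       seed = 1)
metrics <- read.csv(file.path(out, "metrics1.csv"))
model <- get_cell_model("mincell")
proto <- pacing_protocol(n_beats = 30)

## Th_EAD on a subsample (desk scale: 64 drugs, 2.5% grid)
set.seed(1)
idx <- sample(nrow(pop$samples), 64)
th <- vapply(idx, function(i) {
  bl <- do.call(block_vector, as.list(pop$samples[i, ]))
  tryCatch(ead_threshold(model, bl, proto, grid_step = 2.5)$threshold,
           error = function(e) NA_real_)
}, numeric(1))
ead_df <- data.frame(sample = idx, th_ead = th)
write.csv(ead_df, file.path(out, "ead1.csv"), row.names = FALSE)
cat(sprintf("Th_EAD,hERG on %d drugs: %d with EAD below 100%%, median %.1f%%\n",
            length(th), sum(!is.na(th)), median(th, na.rm = TRUE)))

## MCF 1: behavioural (EAD-) vs non-behavioural (EAD+) at a fixed
## perturbation level (the median threshold)
lvl <- median(th, na.rm = TRUE)
beh <- ifelse(is.na(th) | th > lvl, "EAD-", "EAD+")
if (length(unique(beh)) == 2) {
  mc_ead <- mcf_rank(pop$samples[idx, ], beh,
                     contrasts = list(c("EAD-", "EAD+")))
  top <- mc_ead[order(-mc_ead$D), ][1:3, ]
  cat("EAD-based MCF, top parameters:",
      paste(sprintf("%s (D=%.2f)", top$parameter, top$D), collapse = ", "),
      "\n")
  write.csv(mc_ead, file.path(out, "mcf_ead.csv"), row.names = FALSE)
}

## MCF 2: qNet-defined tertiles over the full population
ok <- !is.na(metrics$qNet)
ter <- cut(metrics$qNet[ok],
           quantile(metrics$qNet[ok], c(0, 1/3, 2/3, 1)),
           labels = c("high", "intermediate", "low"), include.lowest = TRUE)
mc_q <- mcf_rank(pop$samples[ok, ], as.character(ter),
                 contrasts = list(c("low", "intermediate"),
                                  c("high", "intermediate")))
write.csv(mc_q, file.path(out, "mcf_qnet.csv"), row.names = FALSE)
for (ct in unique(mc_q$contrast)) {
  sub <- mc_q[mc_q$contrast == ct, ]
  top <- sub[order(-sub$D), ][1:3, ]
  cat(sprintf("qNet MCF %s: %s\n", ct,
              paste(sprintf("%s (D=%.2f)", top$parameter, top$D),
                    collapse = ", ")))
}
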