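#!/usr/bin/env Rscript
# NE synchrony: per-cell sliding local:global correlation (30 s window),
# high/low regime segmentation from the cell-average trace, low-period
# durations, and the synchrony-correlation vs distance profile.

library(neflow)

ses <- "results/session"
pre <- readRDS(file.path(ses, "preprocessed.rds"))
ts <- pre$traces
n <- nrow(ts$cell_ca)

syn <- t(sapply(seq_len(n), function(i)
  sliding_correlation(ts$local_ne[i, ], ts$global_ne[i, ], ts$frame_hz,
                      window_s = 30)))
reg <- segment_regimes(syn, ts$frame_hz)
cat(sprintf("%d cells; %d low-synchrony periods, median length %.1f s (range %.1f-%.1f)\n",
            n, length(reg$low_period_s), median(reg$low_period_s),
            min(reg$low_period_s), max(reg$low_period_s)))

prof <- synchrony_distance_profile(syn, pre$geometry$centers, ts$geometry$px_um)
fit <- lm(r ~ distance_um, data = prof)
cat(sprintf("synchrony-trace correlation vs distance: slope %.4f /um (p = %.3g)\n",
            coef(fit)[2], summary(fit)$coefficients[2, 4]))

out <- data.frame(frame = seq_len(ncol(syn)), average = reg$average,
                  regime = ifelse(reg$low, "low",
                                  ifelse(reg$high, "high", NA)))
write.csv(out, file.path(ses, "synchrony_average.csv"), row.names = FALSE)
write.csv(prof, file.path(ses, "synchrony_distance.csv"), row.names = FALSE)
jsonlite::write_json(
  list(low_period_s = reg$low_period_s,
       distance_slope = unname(coef(fit)[2])),
  file.path(ses, "synchrony_summary.json"), auto_unbox = TRUE, digits = NA)
saveRDS(list(synchrony = syn, regimes = reg), file.path(ses, "synchrony.rds"))
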