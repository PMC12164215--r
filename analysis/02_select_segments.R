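#!/usr/bin/env Rscript
# Stage 2: windowed-lagged cross-correlation synchrony and balanced segment
# selection. Candidate 10-s segments (1-s steps) are filtered to the middle
# 50% of overall motion per dyad; the 4 highest- and 4 lowest-synchrony
# non-overlapping segments per dyad become the high/low stimulus conditions.
# A Bayes-factor t-test then checks that the two dyad types are balanced in
# synchrony and overall motion, as the stimulus set requires.
#
# Reads:  results/motion_series.csv
# Writes: results/segments.csv, results/segment_balance.csv

library(dyadsync)

series <- read_mea_csv("results/motion_series.csv")
ids <- vapply(series, `[[`, character(1), "dyad_id")
dyads <- lapply(unique(ids), function(d) {
  pair <- series[ids == d]
  persons <- vapply(pair, `[[`, character(1), "person_id")
  list(a = pair[[which(persons == "A")]], b = pair[[which(persons == "B")]],
       dyad_type = if (d %in% sprintf("d%02d", 1:4)) "mixed" else "non-autistic")
})
names(dyads) <- unique(ids)

segments <- select_segments(dyads, window_s = 10, lag_s = 3, step_s = 1, k = 4)
write.csv(segments, "results/segments.csv", row.names = FALSE)
message(sprintf("%d segments selected (%d high / %d low)", nrow(segments),
                sum(segments$condition == "high"), sum(segments$condition == "low")))

bal <- do.call(rbind, lapply(c("ips_peak", "overall_motion"), function(m) {
  x <- segments[[m]][segments$dyad_type == "mixed"]
  y <- segments[[m]][segments$dyad_type == "non-autistic"]
  data.frame(measure = m,
             mean_mixed = mean(x), sd_mixed = sd(x),
             mean_nonaut = mean(y), sd_nonaut = sd(y),
             log_bf10 = as.numeric(bayes_t_test(x, y)))
}))
write.csv(bal, "results/segment_balance.csv", row.names = FALSE)
message(sprintf(
  "synchrony balance: mixed %.2f +- %.2f vs non-autistic %.2f +- %.2f, log BF10 = %.2f (%s)",
  bal$mean_mixed[1], bal$sd_mixed[1], bal$mean_nonaut[1], bal$sd_nonaut[1],
  bal$log_bf10[1],
  if (bal$log_bf10[1] < 0) "favours no dyad-type difference" else "favours a difference"))
message(sprintf(
  "overall motion: mixed %.3f +- %.3f vs non-autistic %.3f +- %.3f, log BF10 = %.2f",
  bal$mean_mixed[2], bal$sd_mixed[2], bal$mean_nonaut[2], bal$sd_nonaut[2],
  bal$log_bf10[2]))
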