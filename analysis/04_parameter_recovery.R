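#!/usr/bin/env Rscript
# Stage 4: parameter recovery at the published sample size. Ratings are
# generated with the study's point estimates as ground truth (dyad type
# -3.87, synchrony 0.83 on +/-1 codes; 30+30 observers) and the rating
# model must cover them; saccade counts are generated at the published
# group rates (ASD 17.7, COMP 20.2 per 10-s segment) and the Poisson model
# must recover the rates.
#
# Writes: results/recovery_ratings.csv, results/recovery_saccades.csv

library(dyadsync)
dir.create("results", showWarnings = FALSE)

des <- study_design(n_observers_per_group = c(30, 30), seed = 42)
agg <- prepare_behavioural_table(gen_ratings(des))
fit <- fit_mixed_model(agg, model_spec(
  "rating", ~ group_c * dyad_type_c * ips_c,
  list(participant_id = "1", dyad_id = "1"),
  chains = 3, draws = 2000, warmup = 1000, seed = 43))
ps <- posterior_summary(fit)
ps$truth <- c("b_dyad_type_c" = -3.87, "b_ips_c" = 0.83,
              "b_group_c" = 1.07)[ps$parameter]
write.csv(ps, "results/recovery_ratings.csv", row.names = FALSE)
dt <- ps[ps$parameter == "b_dyad_type_c", ]
message(sprintf("dyad-type coefficient: %.2f [%.2f, %.2f], truth -3.87 %s",
                dt$mean, dt$lower, dt$upper,
                if (dt$lower <= -3.87 && -3.87 <= dt$upper) "(covered)" else "(missed)"))
md <- marginal_difference(fit, "dyad_type_c")
message(sprintf("marginal mixed - non-autistic rating difference: %.2f [%.2f, %.2f]",
                mean(md), quantile(md, 0.025), quantile(md, 0.975)))

set.seed(44)
tab <- expand.grid(participant_id = sprintf("s%02d", 1:24),
                   dyad_id = sprintf("d%d", 1:8),
                   condition = c("high", "low"), segment = 1:4,
                   stringsAsFactors = FALSE)
tab$group <- ifelse(as.integer(sub("s", "", tab$participant_id)) <= 12, "ASD", "COMP")
tab$dyad_type <- ifelse(tab$dyad_id %in% sprintf("d%d", 1:4), "mixed", "non-autistic")
tab$n_saccades <- rpois(nrow(tab), ifelse(tab$group == "ASD", 17.7, 20.2))
fitp <- fit_mixed_model(tab, model_spec(
  "n_saccades", ~ group_c * dyad_type_c * ips_c,
  list(participant_id = "1", dyad_id = "1"), likelihood = "poisson",
  chains = 2, draws = 1500, warmup = 1000, seed = 45))
mdp <- marginal_difference(fitp, "group_c")
rates <- data.frame(
  group = c("ASD", "COMP"), truth = c(17.7, 20.2),
  mean = c(mean(attr(mdp, "rate_plus")), mean(attr(mdp, "rate_minus"))),
  lower = c(quantile(attr(mdp, "rate_plus"), 0.025), quantile(attr(mdp, "rate_minus"), 0.025)),
  upper = c(quantile(attr(mdp, "rate_plus"), 0.975), quantile(attr(mdp, "rate_minus"), 0.975)))
write.csv(rates, "results/recovery_saccades.csv", row.names = FALSE)
message(sprintf("saccade rates: ASD %.1f [%.1f, %.1f] (truth 17.7); COMP %.1f [%.1f, %.1f] (truth 20.2)",
                rates$mean[1], rates$lower[1], rates$upper[1],
                rates$mean[2], rates$lower[2], rates$upper[2]))
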