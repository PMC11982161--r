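#!/usr/bin/env Rscript
# Step 1: simulate the full study design — 50 unacquainted same-sex dyads,
# each holding three 5-minute conversations (introduction, self-disclosure,
# argumentative) — as coupled binary speech/silence series at 1 Hz, with
# standardized Extraversion/Agreeableness scores per participant and 1-5
# appraisal items generated from the realized coordination.
#
# Writes: results/traits.csv, results/series.csv (long format),
#         results/appraisals.csv

library(dyadcrqa)

dir.create("results", showWarnings = FALSE)
cfg <- study_sim_config(seed = 20260920)
study <- simulate_study(cfg)

write.csv(study$traits, "results/traits.csv", row.names = FALSE)
write.csv(study$appraisals, "results/appraisals.csv", row.names = FALSE)

series_long <- do.call(rbind, lapply(study$series, function(d) {
  do.call(rbind, lapply(list(d$series_a, d$series_b), function(s) {
    data.frame(dyad_id = s$dyad_id, task = s$task,
               participant_id = s$participant_id,
               second_index = seq_along(s$values) - 1L, value = s$values)
  }))
}))
write.csv(series_long, "results/series.csv", row.names = FALSE)

cat(sprintf(
  "Simulated %d dyads x %d tasks (%d series, %d s each); %d participants, %d appraisal rows.\n",
  cfg$n_dyads, length(cfg$tasks), length(study$series), cfg$n_seconds,
  nrow(study$traits), nrow(study$appraisals)))
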