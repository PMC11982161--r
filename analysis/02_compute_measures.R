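#!/usr/bin/env Rscript
# Step 2: rebuild the dyadic series from the persisted long CSV and compute
# the five coordination measures per dyad-task (global and lag-zero
# recurrence rate, profile quotient, laminarity and trapping-time
# asymmetries), plus the directional raw values behind them.
#
# Reads:  results/series.csv
# Writes: results/measures.csv

library(dyadcrqa)

series <- read.csv("results/series.csv", stringsAsFactors = FALSE)
keys <- unique(series[, c("dyad_id", "task")])

measures <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
  sub <- series[series$dyad_id == keys$dyad_id[i] &
                  series$task == keys$task[i], ]
  parts <- sort(unique(sub$participant_id))
  stopifnot(length(parts) == 2)
  mk <- function(p) {
    rows <- sub[sub$participant_id == p, ]
    rows <- rows[order(rows$second_index), ]
    speech_series(rows$value, dyad_id = keys$dyad_id[i],
                  participant_id = p, task = keys$task[i])
  }
  dyad_measures(align_dyad(mk(parts[1]), mk(parts[2])))
}))

write.csv(measures, "results/measures.csv", row.names = FALSE)

cat(sprintf("Computed measures for %d dyad-task series.\n", nrow(measures)))
cat("Per-task means:\n")
print(aggregate(measures[, c("rr_global", "rr_los", "q_dcrp", "lam_ard",
                             "tt_ard")],
                by = list(task = measures$task), FUN = mean), digits = 3)
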