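#!/usr/bin/env Rscript
# Step 5: appraisal models. Each 1-5 item is modeled per participant with
# general linear models on the dyad's standardized role-based trait scores
# and one coordination predictor (lag-zero coordination by default),
# including the two- and three-way interactions; p-values are
# Benjamini-Hochberg corrected across the whole item family.
#
# Reads:  results/measures.csv, results/traits.csv, results/appraisals.csv
# Writes: results/models_appraisals.csv

library(dyadcrqa)

measures <- read.csv("results/measures.csv", stringsAsFactors = FALSE)
traits <- read.csv("results/traits.csv", stringsAsFactors = FALSE)
appraisals <- read.csv("results/appraisals.csv", stringsAsFactors = FALSE)
study <- list(measures = measures, traits = traits, appraisals = appraisals)

items <- unique(appraisals$item)
fits <- lapply(items, function(item) {
  dat <- assemble_appraisal_table(study, item)
  fit_appraisal_model(dat, item, "trait_a * trait_b * rr_los")
})
fits <- adjust_model_family(fits)

out <- do.call(rbind, Map(function(item, f) {
  cbind(item = item, f$coefficients, r2 = f$marginal_r2)
}, items, fits))
write.csv(out, "results/models_appraisals.csv", row.names = FALSE)

cat("Appraisal GLMs (one model per item, family-wise BH correction):\n")
print(out[out$term != "(Intercept)",
          c("item", "term", "B", "beta", "t", "p", "p_adjusted")],
      digits = 3, row.names = FALSE)
sig <- out$term != "(Intercept)" & out$p_adjusted < 0.05
cat(sprintf("\n%d of %d non-intercept terms survive BH at 5%% FDR.\n",
            sum(sig), sum(out$term != "(Intercept)")))
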