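#!/usr/bin/env Rscript
# Stage 2: exclusions, KDM training, biological-age scoring.
#
# Applies the analytic exclusions (age > 45, complete cases), trains the
# Klemera-Doubal model on the complete-case sample, scores biological age
# and its residual-based acceleration, and serializes the model.

library(kdmcohort)

cohort <- read.csv("results/cohort.csv")
cfg <- analysis_config()
excl <- apply_exclusions(cohort, cfg)

cat("exclusion flowchart:\n")
print(excl$report, row.names = FALSE)

model <- fit_kdm(excl$kdm, cfg$biomarkers)
scores <- compute_kdm(model, excl$kdm)
scores <- compute_age_acceleration(scores, excl$kdm)

cat(sprintf("\ns_ba = %.3f years (%s); %d participants scored\n",
            model$s_ba, model$sba_method, nrow(scores)))
cat(sprintf("KDM age: mean %.1f (chronological %.1f); %.1f%% accelerated\n",
            mean(scores$kdm_age),
            mean(excl$kdm$chronological_age),
            100 * mean(scores$accelerated)))

write_kdm_model(model, "results/kdm_model.tsv")
write.table(scores, "results/kdm_scores.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
writeLines(capture.output(print(excl$report, row.names = FALSE)),
           "results/exclusion_flowchart.txt")
cat("wrote results/kdm_model.tsv, results/kdm_scores.tsv, results/exclusion_flowchart.txt\n")
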