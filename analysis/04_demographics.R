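#!/usr/bin/env Rscript
# Step 4: demographic summaries.
#
# First a worked example on the published cohort's printed counts (50,801
# patients with the index condition), reproducing its percentages from the
# raw numbers; then the same summary for the simulated cohort of step 1.

library(comorbnet)

counts <- read.delim(system.file("extdata", "table1_demographics.tsv",
                                 package = "comorbnet"))
published <- summarize_demographics(counts = counts)
write.csv(published, "results/demographics_published.csv", row.names = FALSE)
cat("published cohort:\n")
print(published, row.names = FALSE)

cohort <- read_cohort("results/cohort")
patients <- do.call(rbind, lapply(cohort$matrices, function(dm) {
  data.frame(patient_id = rownames(dm$indicators), sex = dm$sex,
             age_band = dm$age_band)
}))
simulated <- summarize_demographics(patients = patients)
write.csv(simulated, "results/demographics_simulated.csv", row.names = FALSE)
cat("\nsimulated cohort:\n")
print(simulated, row.names = FALSE)
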