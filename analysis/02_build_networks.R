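#!/usr/bin/env Rscript
# Step 2: build one comorbidity network per stratum.
#
# Reads the simulated cohort from step 1, keeps diseases with stratum
# prevalence > 1%, estimates the tetrachoric correlation of every disease
# pair, and draws an edge where the likelihood-ratio test of zero
# correlation rejects at p < 0.01 with positive correlation. Networks are
# exported as GraphML and GEXF (node size <- prevalence, edge width <-
# correlation in downstream visualization tools) plus an adjacency CSV.

library(comorbnet)

cohort <- read_cohort("results/cohort")
dir.create("results/networks", recursive = TRUE, showWarnings = FALSE)

summary_rows <- lapply(names(cohort$matrices), function(key) {
  dm <- prevalence_filter(cohort$matrices[[key]], min_prev = 0.01)
  net <- build_network(dm, alpha = 0.01)
  stem <- gsub("[^0-9A-Za-z]", "_", key)
  write_network_graphml(net, sprintf("results/networks/%s.graphml", stem))
  write_network_gexf(net, sprintf("results/networks/%s.gexf", stem))
  write_adjacency_csv(net, sprintf("results/networks/%s_adjacency.csv", stem))
  data.frame(stratum = key, n_patients = net$n_patients,
             nodes = nrow(net$nodes), edges = nrow(net$edges),
             median_rho = stats::median(net$edges$rho))
})
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/network_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat("networks written to results/networks\n")
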