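#!/usr/bin/env Rscript
# Step 3: extract comorbidity patterns by Louvain modularity optimization.
#
# Reads each stratum's network back from GraphML, runs the Louvain method
# (best of 5 seeded restarts), writes the partition TSVs and a per-pattern
# report, and scores recovery of the planted blocks from step 1 by the
# adjusted Rand index.

library(comorbnet)

cohort <- read_cohort("results/cohort")
truth <- cohort$truth$blocks
files <- list.files("results/networks", pattern = "\\.graphml$",
                    full.names = TRUE)
dir.create("results/partitions", recursive = TRUE, showWarnings = FALSE)

networks <- list()
partitions <- list()
scores <- NULL
for (f in files) {
  net <- read_network_graphml(f)
  key <- paste0(net$sex, ":", net$age_band)
  part <- louvain(net, seed = 20240101 + match(f, files), n_restarts = 5)
  write_partition_tsv(part, file.path("results/partitions",
                                      sub("\\.graphml$", ".tsv", basename(f))))
  ari <- mclust::adjustedRandIndex(part$assignment[names(truth)], truth)
  scores <- rbind(scores, data.frame(stratum = key,
                                     patterns = length(unique(part$assignment)),
                                     modularity = part$q, ari = ari))
  networks[[key]] <- net
  partitions[[key]] <- part
}

report <- pattern_report(networks, partitions)
write.csv(report, "results/pattern_report.csv", row.names = FALSE)
write.csv(scores, "results/pattern_recovery.csv", row.names = FALSE)
print(scores, row.names = FALSE)
cat(sprintf("planted 3-block structure recovered with mean ARI %.3f\n",
            mean(scores$ari)))
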