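#!/usr/bin/env Rscript
# Enumerate the five regulatory circuit schemes as concrete mass-action
# reaction networks and tabulate their reactions and rates.
# Output: results/networks.csv

suppressPackageStartupMessages(library(circuitnoise))
dir.create("results", showWarnings = FALSE)

rows <- do.call(rbind, lapply(circuit_schemes(), function(s) {
  net <- build_network(s, inducer = 1000)
  data.frame(scheme = s, reaction = net$reactions,
             rate_per_s = net$rates_vec,
             translation = net$is_translation)
}))
write.csv(rows, "results/networks.csv", row.names = FALSE)

counts <- table(rows$scheme)
cat("Reactions per scheme:\n")
print(counts[circuit_schemes()])
cat("\nThe constitutive circuit is a plain 4-reaction expression cycle;\n",
    "the bicistronic autoregulation circuit adds repressor translation\n",
    "from the same transcript (11 reactions); the hybrid adds a weak,\n",
    "never-repressed second promoter for the repressor (14 reactions).\n",
    sep = "")
cat("Wrote results/networks.csv\n")
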