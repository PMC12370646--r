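#!/usr/bin/env Rscript
# Simulate a small demonstration cohort and write it in the package's CSV
# dialect (one file per participant per sensor, plus labels, ground-truth
# sections and a manifest). Larger cohorts are generated in memory by the
# later stages; this script exists to show the on-disk layout.

suppressMessages(library(gaitupdrs))

out <- "results/cohort_demo"
cohort <- simulate_cohort(4, protocol_config(), seed = 42)
write_cohort(cohort, out)

cat("cohort of", nrow(cohort$labels), "participants written to", out, "\n")
cat("score table:\n")
print(cohort$labels[, c("participant", item_names())], row.names = FALSE)
sec <- cohort$participants[[1]]$truth$sections
cat("participant P001 has", sum(sec$kind == "SW"), "straight-walk and",
    sum(sec$kind == "T"), "turn sections\n")
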