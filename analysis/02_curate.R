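#!/usr/bin/env Rscript
# Curate the raw records: DOI-length filter, taxonomy keyword resolution
# with the fixed priority order, restriction to plant/fungi/bacteria, and
# molecular profiling (MW, Fsp3, AlogP, H-bond counts, TPSA, glycoside and
# peptide SMARTS flags, prioritized category).

suppressMessages(library(nporigin))

cfg <- pipeline_config()
run_curate(cfg, "results/run/dataset.csv", "results/run/curated.csv")
cur <- utils::read.csv("results/run/curated.csv")

cat("\nPrioritized category by origin (fractions):\n")
print(round(prop.table(table(cur$origin, cur$category), margin = 1), 3))

cat("\nShare of molecules at MW <= 200 by origin:\n")
print(round(tapply(cur$mw <= 200, cur$origin, mean), 3))

write.csv(as.data.frame.matrix(table(cur$origin, cur$category)),
          "results/category_by_origin.csv")
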