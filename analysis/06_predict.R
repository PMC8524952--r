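#!/usr/bin/env Rscript
# Train the final classifier on the full curated set and query it with a
# few structures: a pentapeptide, a flavone glucoside, and a small
# polyketide-like aromatic.

suppressMessages(library(nporigin))

cfg <- pipeline_config()
run_train(cfg, "results/run/curated.csv", "results/run/fingerprints.csv",
          "results/run/model.rds")

queries <- c(
  pentapeptide      = "NCC(=O)NC(C)C(=O)NC(CC(C)C)C(=O)NCC(=O)NC(CO)C(=O)O",
  flavone_glucoside = "O=C1C=C(c2ccc(OC3OC(CO)C(O)C(O)C3O)cc2)Oc2cc(O)cc(O)c12",
  orsellinic_methyl = "Cc1cc(O)cc(O)c1C(=O)O"
)
cat("\nPredictions (label, then per-class percentages):\n")
res <- run_predict("results/run/model.rds", unname(queries))
res$query <- names(queries)
write.csv(res, "results/predictions.csv", row.names = FALSE)
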