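#!/usr/bin/env Rscript
# Evaluate the one-vs-rest SVM with the MAP4 match-fraction kernel by
# stratified 5-fold cross-validation (inner 5-fold C selection per training
# set), and compare against the three comparator encodings: folded circular
# substructure bits (Tanimoto kernel), folded atom-pair bits (Tanimoto
# kernel) and the 11-descriptor property vector (RBF kernel).

suppressMessages(library(nporigin))

cfg <- pipeline_config()
cur <- utils::read.csv("results/run/curated.csv")
fp <- read_fingerprints("results/run/fingerprints.csv")

cv <- run_crossval(cfg, "results/run/curated.csv",
                   "results/run/fingerprints.csv", "results/crossval_map4")
cat("\nMAP4 SVM:\n"); print(cv)

comparators <- list(
  circular = list(X = comparator_fingerprint(cur$smiles, "circular"),
                  spec = kernel_spec("tanimoto"), rep = "circular"),
  atom_pair = list(X = comparator_fingerprint(cur$smiles, "atom_pair"),
                   spec = kernel_spec("tanimoto"), rep = "atom_pair"),
  properties = list(X = property_vector(cur$smiles),
                    spec = kernel_spec("rbf"), rep = "property")
)
rows <- list(data.frame(model = "map4", cv$summary))
for (nm in names(comparators)) {
  cc <- comparators[[nm]]
  cvc <- cross_validate_origin(cc$X, cur$origin, spec = cc$spec,
                               k = cfg$classifier$folds,
                               seed = cfg$classifier$seed,
                               C_grid = cfg$classifier$C_grid,
                               validation = "holdout",
                               representation = cc$rep)
  cat("\n", nm, "SVM:\n"); print(cvc)
  rows[[length(rows) + 1]] <- data.frame(model = nm, cvc$summary)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/svm_comparison.csv", row.names = FALSE)
cat("\nwrote results/svm_comparison.csv\n")
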