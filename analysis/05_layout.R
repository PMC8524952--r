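#!/usr/bin/env Rscript
# Build the chemical-space map: LSH forest (32 trees) over the MinHash
# fingerprints, 20-approximate-nearest-neighbor graph, minimum spanning
# tree, 2D tree layout, and one colored export per channel (MW, Fsp3,
# AlogP, origin, category).

suppressMessages(library(nporigin))

cfg <- pipeline_config()
lay <- run_layout(cfg, "results/run/curated.csv",
                  "results/run/fingerprints.csv", "results/chemspace")

n <- nrow(lay$coordinates)
cat(sprintf("\nLayout: %d molecules, %d kNN edges, %d tree edges\n",
            n, nrow(lay$knn_edges), nrow(lay$mst_edges)))
cat(sprintf("Mean MST edge weight (1 - similarity): %.3f\n",
            mean(lay$mst_edges$weight)))

# how often does a tree edge connect two molecules of the same origin?
same <- mean(lay$channels$origin[lay$mst_edges$i] ==
             lay$channels$origin[lay$mst_edges$j])
cat(sprintf("Tree edges joining same-origin molecules: %.1f%%\n", 100 * same))
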