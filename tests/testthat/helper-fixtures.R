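# Shared fixtures, computed lazily and cached for the whole test run.
# Sizes are kept small: the fixtures exist to exercise code paths, not to
# re-measure headline numbers (test-acceptance.R does that at full scale).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

small_dataset <- function() {
  cached("small_dataset", generate_dataset(synth_config(n_per_class = 25, seed = 11)))
}

small_fingerprints <- function() {
  cached("small_fp", map4_fingerprint(small_dataset()$smiles))
}

small_profile <- function() {
  cached("small_profile", compute_profile(small_dataset()$smiles))
}

# a clearly separable three-class toy set (distinct scaffold families)
toy_separable <- function() {
  cached("toy_separable", {
    ds <- generate_dataset(synth_config(n_per_class = 15, seed = 5))
    list(dataset = ds, fp = map4_fingerprint(ds$smiles))
  })
}

# constructed MinHash-like fingerprints with three far-apart classes:
# rows of a class share most positions, classes share none, so a working
# classifier must separate them perfectly
block_fingerprints <- function(n_per_class = 15, d = 64, noise = 6) {
  cached(paste0("blocks_", n_per_class, "_", d), {
    set.seed(123)
    base <- lapply(1:3, function(cl) sample.int(1e6, d) + cl * 10000000L)
    X <- do.call(rbind, lapply(1:3, function(cl) {
      t(vapply(seq_len(n_per_class), function(i) {
        v <- base[[cl]]
        idx <- sample.int(d, noise)
        v[idx] <- sample.int(1e6, noise)
        v
      }, integer(d)))
    }))
    list(X = X, labels = rep(c("a", "b", "c"), each = n_per_class))
  })
}

# independent Kruskal MST (union-find), used as the second-algorithm oracle
kruskal_mst_weight <- function(edges) {
  parent <- seq_len(max(edges$i, edges$j))
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  ord <- order(edges$weight, edges$i, edges$j)
  total <- 0
  for (r in ord) {
    ri <- find(edges$i[r])
    rj <- find(edges$j[r])
    if (ri != rj) {
      parent[ri] <- rj
      total <- total + edges$weight[r]
    }
  }
  total
}

# independent re-implementation of the evaluation metrics, written directly
# from the formula definitions (per-class loops, no vectorized shortcuts)
oracle_metrics <- function(cm) {
  k <- nrow(cm)
  recalls <- numeric(k)
  f1s <- numeric(k)
  support <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    recalls[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1s[i] <- if (prec + recalls[i] > 0)
      2 * prec * recalls[i] / (prec + recalls[i]) else 0
    support[i] <- sum(cm[i, ])
  }
  s <- sum(cm)
  cdiag <- sum(diag(cm))
  pk <- colSums(cm)
  tk <- rowSums(cm)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  list(
    balanced_accuracy = mean(recalls),
    f1_weighted = sum(f1s * support) / sum(support),
    mcc = if (den > 0) (cdiag * s - sum(pk * tk)) / den else 0
  )
}

random_confusion <- function(k = 3) {
  matrix(sample.int(50, k * k, replace = TRUE) - 1L, k, k,
         dimnames = list(letters[1:k], letters[1:k]))
}
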