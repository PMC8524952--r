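# End-to-end pipeline wiring: each stage is a pure function of
# (inputs, config) that reads the previous stage's declared outputs and
# writes its own, so re-running with identical inputs reproduces outputs
# byte for byte. The numbered scripts under analysis/ are thin drivers over
# these functions.

#' Assemble a pipeline configuration
#'
#' Defaults follow the reference settings throughout: 1024-dimensional
#' MinHash fingerprints of radii 1-2, C grid {0.01, 0.1, 1, 10, 100} with
#' 5-fold validation, 32 LSH trees and 20 approximate neighbors.
#'
#' @param synthetic A [synth_config()].
#' @param fingerprint List with `d`, `radii`, `seed`.
#' @param classifier List with `kernel`, `C_grid`, `folds`, `seed`.
#' @param layout List with `n_trees`, `k`, `seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synth_config(),
                            fingerprint = list(d = 1024L, radii = c(1L, 2L),
                                               seed = 42L),
                            classifier = list(kernel = "map4_match",
                                              C_grid = c(0.01, 0.1, 1, 10, 100),
                                              folds = 5L, seed = 1L),
                            layout = list(n_trees = 32L, k = 20L, seed = 1L)) {
  structure(list(synthetic = synthetic, fingerprint = fingerprint,
                 classifier = classifier, layout = layout),
            class = "pipeline_config")
}

config_manifest <- function(config, path) {
  jsonlite::write_json(lapply(unclass(config), unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stage 1: simulate a labeled dataset
#'
#' Writes `dataset.csv` and `manifest.json` under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Path of the dataset CSV, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config$synthetic)
  path <- file.path(out_dir, "dataset.csv")
  write_dataset(ds, path)
  config_manifest(config, file.path(out_dir, "manifest.json"))
  message("simulate: wrote ", nrow(ds), " molecules to ", path)
  invisible(path)
}

#' Stage 2: curate raw records
#'
#' @param config A [pipeline_config()].
#' @param in_csv Raw records CSV (columns id, smiles, taxonomy, doi).
#' @param out_csv Curated output CSV.
#' @return Path of the curated CSV, invisibly.
#' @export
run_curate <- function(config = pipeline_config(), in_csv, out_csv) {
  records <- read_records(in_csv)
  curated <- curate_records(records)
  n_in <- attr(curated, "n_input")
  n_doi <- attr(curated, "n_after_doi")
  n_skip <- attr(curated, "n_skipped")
  stopifnot(nrow(curated) + n_skip <= n_doi)
  write_curated(curated, out_csv)
  message(sprintf(
    "curate: %d records -> %d with DOI -> %d in plant/fungi/bacteria (%d unparseable skipped)",
    n_in, n_doi, nrow(curated), n_skip))
  invisible(out_csv)
}

#' Stage 3: fingerprint curated molecules
#'
#' @param config A [pipeline_config()].
#' @param curated_csv Curated records CSV.
#' @param out_csv Fingerprint output CSV (sidecar JSON manifest alongside).
#' @return Path of the fingerprint CSV, invisibly.
#' @export
run_fingerprint <- function(config = pipeline_config(), curated_csv, out_csv) {
  curated <- utils::read.csv(curated_csv, stringsAsFactors = FALSE)
  fp <- map4_fingerprint(curated$smiles, d = config$fingerprint$d,
                         radii = config$fingerprint$radii,
                         seed = config$fingerprint$seed)
  write_fingerprints(fp, out_csv, ids = curated$id)
  message("fingerprint: ", nrow(fp), " molecules x ", ncol(fp), " dimensions")
  invisible(out_csv)
}

#' Stage 4: train the origin classifier
#'
#' @param config A [pipeline_config()].
#' @param curated_csv Curated records CSV (labels).
#' @param fp_csv Fingerprint CSV from [run_fingerprint()].
#' @param model_path Output archive path.
#' @return `model_path`, invisibly.
#' @export
run_train <- function(config = pipeline_config(), curated_csv, fp_csv,
                      model_path) {
  curated <- utils::read.csv(curated_csv, stringsAsFactors = FALSE)
  fp <- read_fingerprints(fp_csv)
  model <- fit_origin_classifier(
    fp, curated$origin,
    spec = kernel_spec(config$classifier$kernel),
    C_grid = config$classifier$C_grid,
    folds = config$classifier$folds,
    seed = config$classifier$seed)
  save_origin_classifier(model, model_path)
  message("train: kernel ", model$kernel$kind, ", selected C = ", model$C)
  invisible(model_path)
}

#' Stage 5: cross-validated evaluation
#'
#' Writes `<out_prefix>_folds.csv` (per-fold metrics) and
#' `<out_prefix>_summary.json` (means, standard deviations, per-class
#' recall, pooled confusion matrix).
#'
#' @param config A [pipeline_config()].
#' @param curated_csv Curated records CSV.
#' @param fp_csv Fingerprint CSV.
#' @param out_prefix Output path prefix.
#' @return The `origin_cv` object, invisibly.
#' @export
run_crossval <- function(config = pipeline_config(), curated_csv, fp_csv,
                         out_prefix) {
  curated <- utils::read.csv(curated_csv, stringsAsFactors = FALSE)
  fp <- read_fingerprints(fp_csv)
  cv <- cross_validate_origin(
    fp, curated$origin,
    spec = kernel_spec(config$classifier$kernel),
    k = config$classifier$folds,
    seed = config$classifier$seed,
    C_grid = config$classifier$C_grid)
  utils::write.csv(cv$per_fold, paste0(out_prefix, "_folds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    folds = cv$folds,
    summary = cv$summary,
    per_class_recall = as.list(cv$per_class_recall),
    confusion = as.data.frame(cv$confusion)
  ), paste0(out_prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("crossval: balanced accuracy %.3f +/- %.3f",
                  cv$summary$mean[1], cv$summary$sd[1]))
  invisible(cv)
}

#' Stage 6: chemical-space layout
#'
#' @param config A [pipeline_config()].
#' @param curated_csv Curated records CSV.
#' @param fp_csv Fingerprint CSV.
#' @param out_dir Output directory for CSVs and channel images.
#' @return The `chemspace_layout`, invisibly.
#' @export
run_layout <- function(config = pipeline_config(), curated_csv, fp_csv,
                       out_dir) {
  curated <- utils::read.csv(curated_csv, stringsAsFactors = FALSE)
  fp <- read_fingerprints(fp_csv)
  profile <- curated[, c("mw", "fsp3", "alogp", "category")]
  lay <- chemspace_layout(fp, profile, curated$origin,
                          k = config$layout$k,
                          n_trees = config$layout$n_trees,
                          seed = config$layout$seed)
  export_layout(lay, out_dir)
  message("layout: ", nrow(lay$coordinates), " nodes, ",
          nrow(lay$mst_edges), " tree edges -> ", out_dir)
  invisible(lay)
}

#' Predict the origin of query molecules
#'
#' Prints, per query, `label<TAB>plant=..%,fungi=..%,bacteria=..%` and
#' returns the probabilities.
#'
#' @param model An `origin_classifier` or the path of a saved archive.
#' @param smiles Character vector of query SMILES.
#' @param quiet Suppress printing.
#' @return Data frame from [predict_origin()].
#' @export
run_predict <- function(model, smiles, quiet = FALSE) {
  if (is.character(model)) model <- load_origin_classifier(model)
  res <- predict_origin(model, smiles)
  if (!quiet) {
    for (r in seq_len(nrow(res))) {
      pct <- vapply(model$classes, function(cl)
        sprintf("%s=%.1f%%", cl, 100 * res[[cl]][r]), character(1))
      cat(res$label[r], "\t", paste(pct, collapse = ","), "\n", sep = "")
    }
  }
  invisible(res)
}
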