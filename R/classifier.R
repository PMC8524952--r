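# One-vs-rest SVM over a precomputed kernel with Platt-scaled probabilities.
# The quadratic program is solved by kernlab's C-SVC; kernel construction,
# class weighting, C selection, calibration and the multiclass wrapper live
# here.

#' Kernel specification
#'
#' @param kind `"map4_match"` (MinHash index-match fraction),
#'   `"tanimoto"` or `"dice"` (bit-vector kernels), or `"rbf"` (on scaled
#'   property vectors).
#' @param gamma RBF width; only meaningful for `kind = "rbf"`. `NULL` lets
#'   [fit_origin_classifier()] select it from its `gamma_grid`; computing a
#'   kernel matrix requires a concrete value.
#' @return A list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("map4_match", "tanimoto", "dice", "rbf"),
                        gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (!is.null(gamma) && (!is.finite(gamma) || gamma <= 0))
      stop("rbf kernel requires a positive gamma")
  } else if (!is.null(gamma)) {
    stop("gamma is only meaningful for the rbf kernel")
  }
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

#' Compute a kernel (similarity) matrix between two representation sets
#'
#' @param X,Y Representation matrices (rows = molecules): MinHash integer
#'   fingerprints for `map4_match`, 0/1 bit matrices for `tanimoto`/`dice`,
#'   numeric (pre-scaled) property matrices for `rbf`. `Y = NULL` means
#'   `Y = X`.
#' @param spec A [kernel_spec()].
#' @return `nrow(X) x nrow(Y)` similarity matrix.
#' @export
compute_kernel_matrix <- function(X, Y = NULL, spec = kernel_spec("map4_match")) {
  if (is.null(Y)) Y <- X
  if (!is.matrix(X) || !is.matrix(Y) || ncol(X) != ncol(Y))
    stop("representation mismatch: X and Y must be matrices with equal columns")
  switch(spec$kind,
    map4_match = match_fraction_cpp(X, Y),
    tanimoto = {
      inter <- X %*% t(Y)
      uni <- outer(rowSums(X > 0), rowSums(Y > 0), "+") - inter
      out <- ifelse(uni > 0, inter / uni, 0)
      unname(out)
    },
    dice = {
      inter <- X %*% t(Y)
      tot <- outer(rowSums(X > 0), rowSums(Y > 0), "+")
      out <- ifelse(tot > 0, 2 * inter / tot, 0)
      unname(out)
    },
    rbf = {
      if (is.null(spec$gamma)) stop("rbf kernel matrix requires a concrete gamma")
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      d2[d2 < 0] <- 0
      unname(exp(-spec$gamma * d2))
    })
}

# ---- internal pieces --------------------------------------------------------

# column scaler (zero mean, unit variance), fit on training rows only
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}
apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("stratification error: class(es) smaller than the number of folds: ",
         paste(names(counts)[counts < k], collapse = ", "))
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

# Platt (1999) sigmoid fit with regularized targets: p = 1/(1 + exp(A f + B))
platt_fit <- function(decision, y01) {
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  t_ <- ifelse(y01 == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1] * decision + par[2]
    logp <- -ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))  # log(1/(1+e^z))
    log1mp <- logp + z                                          # log(e^z/(1+e^z))
    -sum(t_ * logp + (1 - t_) * log1mp)
  }
  init <- c(A = 0, B = log((n0 + 1) / (n1 + 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

platt_prob <- function(decision, params) {
  z <- params$A * decision + params$B
  1 / (1 + exp(z))
}

# one binary C-SVC on a precomputed kernel; returns enough to recompute
# decision values as K[new, sv] %*% coef - b
fit_binary_svm <- function(K, y01, C, weights) {
  yf <- factor(ifelse(y01 == 1, "pos", "rest"), levels = c("pos", "rest"))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc", C = C,
                     class.weights = weights)
  sv <- kernlab::SVindex(m)
  coef <- kernlab::coef(m)[[1]]
  b <- kernlab::b(m)
  dec_train <- as.numeric(K[, sv, drop = FALSE] %*% coef - b)
  # orient so that positive decision favors the positive class
  flip <- if (mean(dec_train[y01 == 1]) < mean(dec_train[y01 == 0])) -1 else 1
  list(sv = sv, coef = coef * flip, b = b * flip, C = C)
}

svm_decision <- function(bin, K_new_train) {
  as.numeric(K_new_train[, bin$sv, drop = FALSE] %*% bin$coef - bin$b)
}

# fit the one-vs-rest ensemble at a fixed C on a precomputed kernel
fit_ovr <- function(K, labels, classes, C) {
  lapply(classes, function(cl) {
    y01 <- as.integer(labels == cl)
    n1 <- sum(y01 == 1)
    n0 <- sum(y01 == 0)
    n <- n1 + n0
    w <- c(pos = n / (2 * n1), rest = n / (2 * n0))
    fit_binary_svm(K, y01, C, w)
  })
}

ovr_decisions <- function(models, K_new_train) {
  dec <- vapply(models, svm_decision, numeric(nrow(K_new_train)),
                K_new_train = K_new_train)
  matrix(dec, nrow = nrow(K_new_train))  # vapply drops to vector for 1 row
}

# representation encoder used by predict-from-SMILES
encode_molecules <- function(smiles, representation, params) {
  switch(representation,
    map4 = map4_fingerprint(smiles, d = params$d, radii = params$radii,
                            seed = params$seed),
    circular = comparator_fingerprint(smiles, "circular", nbits = params$nbits),
    atom_pair = comparator_fingerprint(smiles, "atom_pair", nbits = params$nbits),
    property = property_vector(smiles),
    stop("unknown representation: ", representation))
}

default_encoder_params <- function(representation, X) {
  switch(representation,
    map4 = list(d = attr(X, "d") %||% ncol(X),
                radii = attr(X, "radii") %||% c(1L, 2L),
                seed = attr(X, "seed") %||% 42L),
    circular = ,
    atom_pair = list(nbits = ncol(X)),
    property = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- public training / prediction ------------------------------------------

#' Train the one-vs-rest origin classifier
#'
#' Selects the regularization constant `C` (and `gamma` for the RBF kernel)
#' by maximizing validation balanced accuracy, refits every one-vs-rest
#' sub-model on the full training set with binary-balanced class weights
#' (inversely proportional to class frequency), and calibrates each
#' sub-model's decision values with Platt scaling.
#'
#' @param X Representation matrix, rows = molecules (see
#'   [compute_kernel_matrix()] for the expected representation per kernel).
#' @param labels Class labels, one per row of `X`.
#' @param spec A [kernel_spec()]. For `rbf`, `gamma` may be `NULL` here and
#'   selected from `gamma_grid`.
#' @param C_grid Candidate regularization constants.
#' @param gamma_grid Candidate RBF widths (RBF kernel only).
#' @param validation `"cv"` (inner stratified cross-validation, default) or
#'   `"holdout"`.
#' @param folds Inner folds for `validation = "cv"`.
#' @param holdout_fraction Validation fraction for `validation = "holdout"`.
#' @param representation One of `"map4"`, `"circular"`, `"atom_pair"`,
#'   `"property"`; stored so that [predict_origin()] can re-encode SMILES.
#' @param encoder_params Parameters of the encoder (defaults recovered from
#'   `X`'s attributes).
#' @param seed Seed controlling fold assignment.
#' @return An object of class `origin_classifier`.
#' @export
fit_origin_classifier <- function(X, labels,
                                  spec = kernel_spec("map4_match"),
                                  C_grid = c(0.01, 0.1, 1, 10, 100),
                                  gamma_grid = c(0.01, 0.1, 1, 10, 100),
                                  validation = c("cv", "holdout"),
                                  folds = 5L,
                                  holdout_fraction = 0.2,
                                  representation = "map4",
                                  encoder_params = NULL,
                                  seed = 1L) {
  validation <- match.arg(validation)
  labels <- as.character(labels)
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("degenerate training set: single class")
  if (any(table(labels) < 2)) stop("degenerate training set: class with < 2 members")
  if (is.null(encoder_params))
    encoder_params <- default_encoder_params(representation, X)

  needs_scaling <- spec$kind == "rbf"
  gamma_candidates <- if (spec$kind == "rbf" && is.null(spec$gamma))
    gamma_grid else if (spec$kind == "rbf") spec$gamma else NA_real_

  # validation splits of the training rows
  splits <- if (validation == "cv") {
    fold <- stratified_folds(labels, folds, seed)
    lapply(seq_len(folds), function(f) list(train = which(fold != f),
                                            test = which(fold == f)))
  } else {
    k <- max(2L, round(1 / holdout_fraction))
    fold <- stratified_folds(labels, k, seed)
    list(list(train = which(fold != 1L), test = which(fold == 1L)))
  }

  # the kernel does not depend on C, so cache it per split (per gamma for rbf)
  split_kernels <- function(sp) {
    lapply(splits, function(s) {
      Xtr <- X[s$train, , drop = FALSE]
      Xte <- X[s$test, , drop = FALSE]
      if (needs_scaling) {
        sc <- fit_scaler(Xtr)
        Xtr <- apply_scaler(Xtr, sc)
        Xte <- apply_scaler(Xte, sc)
      }
      list(Ktr = compute_kernel_matrix(Xtr, spec = sp),
           Kte = compute_kernel_matrix(Xte, Xtr, sp))
    })
  }
  kernel_cache <- if (spec$kind == "rbf") {
    lapply(gamma_candidates, function(gm) split_kernels(kernel_spec("rbf", gm)))
  } else {
    list(split_kernels(spec))
  }
  score_config <- function(C, gamma) {
    ks <- if (spec$kind == "rbf")
      kernel_cache[[match(gamma, gamma_candidates)]] else kernel_cache[[1]]
    mean(vapply(seq_along(splits), function(si) {
      s <- splits[[si]]
      models <- fit_ovr(ks[[si]]$Ktr, labels[s$train], classes, C)
      dec <- ovr_decisions(models, ks[[si]]$Kte)
      pred <- classes[max.col(dec, ties.method = "first")]
      balanced_accuracy(confusion_matrix(labels[s$test], pred, classes))
    }, numeric(1)))
  }

  grid <- expand.grid(C = C_grid, gamma = gamma_candidates)
  scores <- vapply(seq_len(nrow(grid)), function(i)
    score_config(grid$C[i], grid$gamma[i]), numeric(1))
  best <- which(scores == max(scores))[1]  # ties -> smallest C (grid order)
  C_sel <- grid$C[best]
  gamma_sel <- grid$gamma[best]
  final_spec <- if (spec$kind == "rbf") kernel_spec("rbf", gamma_sel) else spec

  scaler <- NULL
  X_fit <- X
  if (needs_scaling) {
    scaler <- fit_scaler(X)
    X_fit <- apply_scaler(X, scaler)
  }
  K <- compute_kernel_matrix(X_fit, spec = final_spec)
  models <- fit_ovr(K, labels, classes, C_sel)
  dec <- ovr_decisions(models, K)
  platt <- lapply(seq_along(classes), function(i)
    platt_fit(dec[, i], as.integer(labels == classes[i])))

  counts <- table(factor(labels, levels = classes))
  class_weights <- as.numeric(length(labels) / (length(classes) * counts))
  names(class_weights) <- classes

  structure(list(
    classes = classes,
    kernel = final_spec,
    C = C_sel,
    class_weights = class_weights,
    models = models,
    platt = platt,
    scaler = scaler,
    X_train = X,
    labels = labels,
    representation = representation,
    encoder_params = encoder_params,
    validation = validation,
    validation_scores = data.frame(grid, balanced_accuracy = scores),
    seed = seed
  ), class = "origin_classifier")
}

#' @export
print.origin_classifier <- function(x, ...) {
  cat("One-vs-rest SVM origin classifier\n")
  cat("  kernel:", x$kernel$kind,
      if (x$kernel$kind == "rbf") sprintf("(gamma = %g)", x$kernel$gamma) else "",
      "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  C =", x$C, " (selected by", x$validation, "balanced accuracy)\n")
  cat("  training molecules:", nrow(x$X_train), "\n")
  invisible(x)
}

# probabilities for pre-encoded representation rows
predict_encoded <- function(model, X_new) {
  Xtr <- model$X_train
  if (!is.null(model$scaler)) {
    X_new <- apply_scaler(X_new, model$scaler)
    Xtr <- apply_scaler(Xtr, model$scaler)
  }
  K <- compute_kernel_matrix(X_new, Xtr, model$kernel)
  dec <- ovr_decisions(model$models, K)
  prob <- vapply(seq_along(model$classes), function(i)
    platt_prob(dec[, i], model$platt[[i]]), numeric(nrow(X_new)))
  prob <- matrix(prob, nrow = nrow(X_new))
  prob <- prob / rowSums(prob)
  colnames(prob) <- model$classes
  prob
}

#' Predict origin class probabilities
#'
#' Queries are canonicalized and stripped of stereochemistry, encoded with
#' the model's representation, passed through every one-vs-rest sub-model,
#' calibrated by Platt scaling and normalized to sum to one.
#'
#' @param model A fitted [fit_origin_classifier()] object.
#' @param smiles Character vector of query SMILES.
#' @return Data frame with `smiles`, the winning `label`, and one
#'   probability column per class.
#' @export
predict_origin <- function(model, smiles) {
  stopifnot(inherits(model, "origin_classifier"))
  flat <- strip_stereo(smiles)
  if (anyNA(flat))
    stop("unparseable SMILES at position(s): ",
         paste(which(is.na(flat)), collapse = ", "))
  X_new <- encode_molecules(flat, model$representation, model$encoder_params)
  prob <- predict_encoded(model, X_new)
  data.frame(smiles = smiles,
             label = model$classes[max.col(prob, ties.method = "first")],
             prob, stringsAsFactors = FALSE)
}

#' @export
predict.origin_classifier <- function(object, newdata, ...) {
  if (is.character(newdata)) return(predict_origin(object, newdata))
  prob <- predict_encoded(object, newdata)
  data.frame(label = object$classes[max.col(prob, ties.method = "first")],
             prob, stringsAsFactors = FALSE)
}

#' Cross-validate the origin classifier
#'
#' Stratified k-fold evaluation: each fold is held out once while the
#' classifier (including its inner C selection) is trained on the remainder.
#' Reports mean and standard deviation of balanced accuracy, MCC and F1
#' across folds, per-class recall and the pooled confusion matrix.
#'
#' @inheritParams fit_origin_classifier
#' @param k Number of outer folds (default 5).
#' @param ... Passed to [fit_origin_classifier()].
#' @return An object of class `origin_cv`.
#' @export
cross_validate_origin <- function(X, labels, spec = kernel_spec("map4_match"),
                                  k = 5L, seed = 1L, ...) {
  labels <- as.character(labels)
  stopifnot(k >= 2, nrow(X) == length(labels))
  fold <- stratified_folds(labels, k, seed)
  classes <- sort(unique(labels))
  per_fold <- vector("list", k)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    model <- fit_origin_classifier(X[tr, , drop = FALSE], labels[tr],
                                   spec = spec, seed = seed + f, ...)
    prob <- predict_encoded(model, X[te, , drop = FALSE])
    pred <- classes[max.col(prob, ties.method = "first")]
    cm <- confusion_matrix(labels[te], pred, classes)
    pooled <- pooled + cm
    per_fold[[f]] <- data.frame(
      fold = f,
      balanced_accuracy = balanced_accuracy(cm),
      mcc = mcc(cm),
      f1 = f1_score(cm),
      C = model$C
    )
  }
  per_fold <- do.call(rbind, per_fold)
  summary <- data.frame(
    metric = c("balanced_accuracy", "mcc", "f1"),
    mean = c(mean(per_fold$balanced_accuracy), mean(per_fold$mcc),
             mean(per_fold$f1)),
    sd = c(stats::sd(per_fold$balanced_accuracy), stats::sd(per_fold$mcc),
           stats::sd(per_fold$f1))
  )
  structure(list(
    folds = k,
    per_fold = per_fold,
    summary = summary,
    per_class_recall = diag(pooled) / rowSums(pooled),
    confusion = pooled,
    fold_assignment = fold
  ), class = "origin_cv")
}

#' @export
print.origin_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$folds))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-18s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  cat("  per-class recall:",
      paste(sprintf("%s %.3f", names(x$per_class_recall),
                    x$per_class_recall), collapse = ", "), "\n")
  invisible(x)
}

#' Persist / restore a trained classifier
#'
#' The archive holds a manifest (kernel spec, classes, C, weights, Platt
#' parameters, encoder configuration) together with the support data;
#' reloading reproduces predictions bit-for-bit.
#'
#' @param model An `origin_classifier`.
#' @param path Archive path (`.rds`).
#' @return `path` invisibly; `load_origin_classifier()` returns the model.
#' @export
save_origin_classifier <- function(model, path) {
  stopifnot(inherits(model, "origin_classifier"))
  payload <- unclass(model)
  payload$.format_version <- 1L
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_origin_classifier
#' @export
load_origin_classifier <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$.format_version))
    stop("not an origin_classifier archive: ", path)
  payload$.format_version <- NULL
  structure(payload, class = "origin_classifier")
}
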