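#' Classifier configuration
#'
#' One algorithm configuration of the evaluation suite. Only the fields
#' relevant to the chosen algorithm are used. LDA and KNN operate on PCA
#' scores of the preprocessed spectra; the other algorithms operate on the
#' full preprocessed spectra.
#'
#' @param algorithm One of `"lda"`, `"knn"`, `"dtree"`, `"rf"`, `"svm"`,
#'   `"plsda"`.
#' @param n_pcs PCA scores used by `lda`/`knn` (defaults: 2 for LDA, 4 for
#'   KNN).
#' @param k_neighbours KNN neighbourhood size.
#' @param n_trees Random-forest tree count.
#' @param kernel SVM kernel: `"rbf"`, `"linear"`, `"poly"`, `"sigmoid"`.
#' @param C,gamma SVM cost and kernel coefficient.
#' @param n_latent_variables PLS-DA latent variables.
#' @param seed Seed for stochastic backends (random forest).
#' @param label Display label; auto-generated when `NULL`.
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm = c("lda", "knn", "dtree", "rf", "svm",
                                     "plsda"),
                       n_pcs = NULL, k_neighbours = 5, n_trees = 100,
                       kernel = c("rbf", "linear", "poly", "sigmoid"),
                       C = 1, gamma = 0.001, n_latent_variables = 7,
                       seed = 1L, label = NULL) {
  algorithm <- match.arg(algorithm)
  kernel <- match.arg(kernel)
  if (is.null(n_pcs)) n_pcs <- if (algorithm == "lda") 2L else 4L
  if (is.null(label)) {
    label <- switch(algorithm,
      lda   = sprintf("LDA(%d PCs)", n_pcs),
      knn   = sprintf("KNN(k=%d)", k_neighbours),
      dtree = "D.Trees",
      rf    = sprintf("RF(N=%d)", n_trees),
      svm   = sprintf("SVM-C(%s) C=%g g=%g", kernel, C, gamma),
      plsda = sprintf("PLS-DA(%d LVs)", n_latent_variables))
  }
  structure(list(algorithm = algorithm, n_pcs = as.integer(n_pcs),
                 k_neighbours = as.integer(k_neighbours),
                 n_trees = as.integer(n_trees), kernel = kernel,
                 C = C, gamma = gamma,
                 n_latent_variables = as.integer(n_latent_variables),
                 seed = as.integer(seed), label = label),
            class = "model_spec")
}

#' The nine default model configurations
#'
#' The standard evaluation suite: LDA on 2 PC scores, KNN on PC scores,
#' decision tree, 100-tree random forest, SVM with rbf/linear/polynomial/
#' sigmoid kernels, and PLS-DA. Hyperparameters differ between the SNV and
#' SNV+detrend runs (KNN k = 5 vs 3; SVM linear C = 10 vs 100; SVM sigmoid
#' C = 10 vs 100; PLS-DA 7 vs 5 latent variables).
#'
#' @param preprocessing `"snv"` or `"snv_detrend"`.
#' @return Named list of nine [model_spec()]s.
#' @export
default_model_suite <- function(preprocessing = c("snv", "snv_detrend")) {
  preprocessing <- match.arg(preprocessing)
  dt <- preprocessing == "snv_detrend"
  list(
    lda         = model_spec("lda", n_pcs = 2),
    knn         = model_spec("knn", k_neighbours = if (dt) 3 else 5),
    dtree       = model_spec("dtree"),
    rf          = model_spec("rf", n_trees = 100),
    svm_rbf     = model_spec("svm", kernel = "rbf", C = 1000, gamma = 0.001),
    svm_linear  = model_spec("svm", kernel = "linear",
                             C = if (dt) 100 else 10, gamma = 1),
    svm_poly    = model_spec("svm", kernel = "poly", C = 0.1, gamma = 0.1),
    svm_sigmoid = model_spec("svm", kernel = "sigmoid",
                             C = if (dt) 100 else 10, gamma = 0.001),
    plsda       = model_spec("plsda", n_latent_variables = if (dt) 5 else 7)
  )
}

#' Train/validation split specification
#'
#' @param train_fraction Fraction assigned to calibration (default 0.70).
#' @param seed Split seed.
#' @param stratified Preserve class proportions (default TRUE).
#' @return A `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.70, seed = 7L, stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = stratified), class = "split_spec")
}

# evaluate fn with an isolated RNG stream, restoring the caller's state
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Split a spectral matrix into calibration and validation sets
#'
#' Disjoint and exhaustive; in stratified mode each class contributes
#' `round(train_fraction * n_class)` calibration samples, preserving class
#' proportions to within one sample per class. Reproducible from the seed.
#'
#' @param sm A `spectral_matrix`.
#' @param spec A [split_spec()].
#' @return List with `calibration` and `validation` spectral matrices and the
#'   calibration row indices (`cal_idx`).
#' @export
split_matrix <- function(sm, spec = split_spec()) {
  stopifnot(inherits(sm, "spectral_matrix"), inherits(spec, "split_spec"))
  n <- nrow(sm$values)
  cal_idx <- with_seed(spec$seed, function() {
    if (spec$stratified) {
      idx <- integer()
      for (cl in levels(droplevels(sm$labels))) {
        rows <- which(sm$labels == cl)
        if (length(rows) < 2)
          stop(sprintf("class %s has < 2 samples; cannot stratify", cl),
               call. = FALSE)
        idx <- c(idx, sample(rows, round(spec$train_fraction * length(rows))))
      }
      sort(idx)
    } else {
      sort(sample(n, round(spec$train_fraction * n)))
    }
  })
  list(calibration = sm_subset(sm, cal_idx),
       validation = sm_subset(sm, setdiff(seq_len(n), cal_idx)),
       cal_idx = cal_idx)
}

#' Train a classifier on a calibration spectral matrix
#'
#' All data-dependent state -- the row-wise preprocessing, the column means
#' used for centring, the PCA used by score-space models -- is fitted on the
#' calibration data only and stored with the model, so later predictions
#' never leak validation information into the fit.
#'
#' @param spec A [model_spec()].
#' @param prep A [preprocessing_spec()].
#' @param cal A calibration `spectral_matrix`.
#' @return A `trained_model`.
#' @export
train_model <- function(spec, prep, cal) {
  stopifnot(inherits(spec, "model_spec"), inherits(prep, "preprocessing_spec"),
            inherits(cal, "spectral_matrix"))
  Xc <- preprocess(cal$values, prep, cal$grid)
  means <- attr(Xc, "column_means")
  labels <- droplevels(cal$labels)
  on_scores <- spec$algorithm %in% c("lda", "knn")
  pca <- NULL
  feats <- Xc
  if (on_scores) {
    maxk <- min(nrow(Xc) - 1L, ncol(Xc))
    if (spec$n_pcs > maxk)
      stop(sprintf("n_pcs = %d exceeds the fittable PCA rank (%d)",
                   spec$n_pcs, maxk), call. = FALSE)
    pca <- pca_fit(Xc, spec$n_pcs)
    feats <- pca$scores
  }
  fit <- switch(spec$algorithm,
    lda = MASS::lda(feats, grouping = labels),
    knn = fit_knn(feats, labels, spec$k_neighbours),
    dtree = {
      df <- data.frame(.y = labels, feats)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                  minbucket = 1, xval = 0))
    },
    rf = with_seed(spec$seed, function()
      randomForest::randomForest(feats, y = labels, ntree = spec$n_trees)),
    svm = e1071::svm(feats, y = labels,
                     kernel = switch(spec$kernel, rbf = "radial",
                                     poly = "polynomial", spec$kernel),
                     cost = spec$C, gamma = spec$gamma, scale = FALSE),
    plsda = fit_plsda(Xc, labels, spec$n_latent_variables)
  )
  structure(list(spec = spec, prep = prep, column_means = means,
                 pca = pca, fit = fit, levels = levels(labels),
                 grid = cal$grid),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %s%s\n", x$spec$label, x$prep$method,
              if (!is.null(x$pca)) sprintf(" (%d PC scores)",
                                           x$spec$n_pcs) else ""))
  invisible(x)
}

#' Predict patty categories for new spectra
#'
#' @param object A `trained_model`.
#' @param newdata `spectral_matrix` or samples x channels matrix of raw
#'   (unpreprocessed) mean spectra.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectral_matrix")) newdata$values
       else as.matrix(newdata)
  Xc <- preprocess(X, object$prep, object$grid, means = object$column_means)
  feats <- if (!is.null(object$pca)) pca_project(object$pca, Xc) else Xc
  pred <- switch(object$spec$algorithm,
    lda = stats::predict(object$fit, feats)$class,
    knn = predict_knn(object$fit, feats),
    dtree = stats::predict(object$fit, data.frame(feats), type = "class"),
    rf = stats::predict(object$fit, feats),
    svm = stats::predict(object$fit, feats),
    plsda = predict_plsda(object$fit, Xc)
  )
  factor(as.character(pred), levels = object$levels)
}

#' Overall multiclass accuracy (%)
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Percentage of agreeing labels.
#' @export
multiclass_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  100 * mean(as.character(y_true) == as.character(y_pred))
}

#' Leave-one-out cross-validation accuracy
#'
#' For every sample the full data-dependent state (preprocessing centring,
#' PCA, classifier) is refitted on the remaining n - 1 samples and the
#' held-out sample is predicted; the result is the percentage predicted
#' correctly.
#'
#' @param spec [model_spec()].
#' @param prep [preprocessing_spec()].
#' @param cal Calibration `spectral_matrix` (>= 2 samples).
#' @return Accuracy in percent.
#' @export
loocv <- function(spec, prep, cal) {
  n <- nrow(cal$values)
  if (n < 2) stop("LOOCV needs >= 2 samples", call. = FALSE)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- train_model(spec, prep, sm_subset(cal, setdiff(seq_len(n), i)))
    pred[i] <- as.character(
      predict(fit, cal$values[i, , drop = FALSE]))
  }
  multiclass_accuracy(cal$labels, pred)
}

# stratified fold assignment for k-fold CV
stratified_folds <- function(labels, k, seed = 1L) {
  with_seed(seed, function() {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fold
  })
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the supplied parameter values with
#' stratified k-fold cross-validation on the calibration set and returns the
#' best-scoring [model_spec()]; ties break in grid order (first wins).
#'
#' @param spec Base [model_spec()]; grid values overwrite its fields.
#' @param grid Named list of parameter value vectors (e.g.
#'   `list(C = c(1, 10, 100), gamma = c(0.001, 0.1))`).
#' @param prep [preprocessing_spec()].
#' @param cal Calibration `spectral_matrix`.
#' @param inner_folds Folds of the inner CV (default 5).
#' @param seed Fold-assignment seed.
#' @return List: `best` (the winning spec), `results` (data.frame of every
#'   grid point and its CV accuracy).
#' @export
grid_search <- function(spec, grid, prep, cal, inner_folds = 5, seed = 1L) {
  stopifnot(length(grid) >= 1, !is.null(names(grid)))
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  fold <- stratified_folds(cal$labels, inner_folds, seed)
  scores <- numeric(nrow(combos))
  for (j in seq_len(nrow(combos))) {
    cand <- spec
    for (par in names(combos)) cand[[par]] <- combos[j, par]
    cand <- do.call(model_spec, c(cand[setdiff(names(cand), "label")],
                                  label = NULL))
    correct <- 0L
    for (f in sort(unique(fold))) {
      tr <- which(fold != f); te <- which(fold == f)
      fit <- train_model(cand, prep, sm_subset(cal, tr))
      pr <- predict(fit, cal$values[te, , drop = FALSE])
      correct <- correct + sum(as.character(pr) ==
                                 as.character(cal$labels[te]))
    }
    scores[j] <- 100 * correct / nrow(cal$values)
  }
  best_j <- which.max(scores)
  best <- spec
  for (par in names(combos)) best[[par]] <- combos[best_j, par]
  best <- do.call(model_spec, c(best[setdiff(names(best), "label")],
                                label = NULL))
  list(best = best, results = cbind(combos, cv_accuracy = scores))
}

#' Evaluate a suite of preprocessing x model combinations
#'
#' Splits the data once (the identical split is reused across every cell),
#' then for every (preprocessing, model) pair reports the calibration
#' resubstitution accuracy (CAL), the leave-one-out cross-validation accuracy
#' on the calibration split (CV, optional), and the accuracy on the untouched
#' validation split (VAL). Validation rows never influence preprocessing
#' statistics, PCA or fitting.
#'
#' @param sm Labelled `spectral_matrix`.
#' @param preprocessings Character vector or list of [preprocessing_spec()]s.
#' @param models `NULL` for the per-preprocessing [default_model_suite()], a
#'   list of [model_spec()]s, or a `function(preprocessing_name)` returning
#'   one.
#' @param split A [split_spec()].
#' @param cv Compute the LOOCV column (default TRUE; the expensive part).
#' @return data.frame of evaluation records: `preprocessing`, `model`,
#'   `cal`, `cv`, `val` (accuracies in %; `cv` is `NA` when skipped), plus
#'   the `regulation` flag on `val`.
#' @export
evaluate_suite <- function(sm, preprocessings = c("snv", "snv_detrend"),
                           models = NULL, split = split_spec(), cv = TRUE) {
  parts <- split_matrix(sm, split)
  recs <- list()
  for (pp in preprocessings) {
    prep <- if (inherits(pp, "preprocessing_spec")) pp
            else preprocessing_spec(pp)
    suite <- if (is.null(models)) default_model_suite(prep$method)
             else if (is.function(models)) models(prep$method)
             else models
    for (ms in suite) {
      fit <- train_model(ms, prep, parts$calibration)
      cal_acc <- multiclass_accuracy(parts$calibration$labels,
                                     predict(fit, parts$calibration))
      val_acc <- multiclass_accuracy(parts$validation$labels,
                                     predict(fit, parts$validation))
      cv_acc <- if (cv) loocv(ms, prep, parts$calibration) else NA_real_
      recs[[length(recs) + 1L]] <- data.frame(
        preprocessing = prep$method, model = ms$label,
        cal = cal_acc, cv = cv_acc, val = val_acc,
        regulation = regulation_flag(val_acc))
    }
  }
  do.call(rbind, recs)
}
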