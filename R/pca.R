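#' Principal component analysis of a centred spectral matrix
#'
#' Singular value decomposition of the column-centred matrix. Loadings are
#' the leading right singular vectors; the explained variance of component k
#' is `100 * sigma_k^2 / sum(sigma_i^2)`. The sign of each component is fixed
#' so its largest-magnitude loading element is positive, making scores and
#' loadings reproducible across runs and platforms. The default component
#' cap of four reflects the screening convention for this kind of spectral
#' data.
#'
#' @param X_centred Column-centred samples x channels matrix (see
#'   [mean_centre()] or [preprocess()]).
#' @param n_components Number of components (<= min(samples - 1, channels)).
#' @return A `pca_model`: `loadings` (channels x k, orthonormal), `scores`
#'   (samples x k), `explained_variance_pct`, `column_means` (from the
#'   centring attribute when present), `eigenvalues` (all PCs, for residual
#'   statistics), `n_samples`.
#' @export
pca_fit <- function(X_centred, n_components = 4) {
  X <- as.matrix(X_centred)
  n <- nrow(X); p <- ncol(X)
  maxk <- min(n - 1L, p)
  if (n_components < 1 || n_components > maxk)
    stop(sprintf("`n_components` must be in [1, %d]", maxk), call. = FALSE)
  sv <- svd(X, nu = 0, nv = n_components)
  d2 <- sv$d^2
  P <- sv$v
  # sign convention: largest-|loading| element positive
  for (k in seq_len(ncol(P))) {
    j <- which.max(abs(P[, k]))
    if (P[j, k] < 0) P[, k] <- -P[, k]
  }
  structure(list(
    loadings = P,
    scores = X %*% P,
    explained_variance_pct = 100 * d2[seq_len(n_components)] / sum(d2),
    eigenvalues = d2 / (n - 1),
    column_means = attr(X_centred, "column_means"),
    n_samples = n,
    n_components = n_components
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; explained variance: %s\n",
              x$n_components,
              paste(sprintf("%.2f%%", x$explained_variance_pct),
                    collapse = ", ")))
  invisible(x)
}

#' Project (new) centred data onto a fitted PCA model
#'
#' @param model A [pca_fit()] model.
#' @param X_centred Matrix centred with the *model's* column means.
#' @return samples x k score matrix.
#' @export
pca_project <- function(model, X_centred) {
  as.matrix(X_centred) %*% model$loadings
}

#' Influence-based outlier screening
#'
#' Flags samples whose Hotelling T-squared (distance within the model plane)
#' exceeds its F-distribution limit, or whose Q residual (distance from the
#' model plane) exceeds the Jackson-Mudholkar limit, at significance level
#' `alpha`. These are the two axes of the chemometric influence plot. The
#' intended calling contract is a single removal-and-refit pass: remove the
#' flagged rows and refit the PCA once.
#'
#' @param model A [pca_fit()] model.
#' @param X_centred The centred matrix the model was fitted on (or new data
#'   centred with the model means).
#' @param alpha Significance level (default 0.01).
#' @param sample_ids Optional ids for the report.
#' @return An `outlier_report`: `flagged` (ids), `t2`, `q` (per-sample
#'   statistics), `t2_limit`, `q_limit`, `alpha`.
#' @export
detect_outliers <- function(model, X_centred, alpha = 0.01,
                            sample_ids = rownames(X_centred)) {
  X <- as.matrix(X_centred)
  n <- nrow(X)
  k <- model$n_components
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  T <- pca_project(model, X)
  lam <- model$eigenvalues[seq_len(k)]
  t2 <- rowSums(sweep(T^2, 2, lam, `/`))
  t2_limit <- k * (model$n_samples - 1) / (model$n_samples - k) *
    stats::qf(1 - alpha, k, model$n_samples - k)

  resid <- X - T %*% t(model$loadings)
  q <- rowSums(resid^2)
  lam_res <- model$eigenvalues[-seq_len(k)]
  lam_res <- lam_res[lam_res > 1e-12 * max(model$eigenvalues)]
  if (length(lam_res) >= 1) {
    th1 <- sum(lam_res); th2 <- sum(lam_res^2); th3 <- sum(lam_res^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
    ca <- stats::qnorm(1 - alpha)
    q_limit <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
                        1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  } else {
    q_limit <- Inf  # full-rank model: no residual subspace
  }
  flagged <- sample_ids[t2 > t2_limit | q > q_limit]
  structure(list(flagged = flagged, t2 = t2, q = q,
                 t2_limit = t2_limit, q_limit = q_limit, alpha = alpha,
                 sample_ids = sample_ids),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d flagged of %d (T2 limit %.3f, Q limit %s)\n",
              length(x$flagged), length(x$t2), x$t2_limit,
              format(x$q_limit, digits = 4)))
  invisible(x)
}

#' One screening pass: fit, flag, remove, refit
#'
#' Convenience wrapper implementing the single removal-and-refit contract of
#' [detect_outliers()] on a spectral matrix.
#'
#' @param sm A `spectral_matrix`.
#' @param spec [preprocessing_spec()] applied before the PCA.
#' @param n_components Components for the screening model.
#' @param alpha Significance level.
#' @return List: `kept` (cleaned `spectral_matrix`), `report`
#'   (the `outlier_report`), `pca` (refitted model on the kept rows).
#' @export
screen_outliers <- function(sm, spec = preprocessing_spec("mean_centre"),
                            n_components = 4, alpha = 0.01) {
  stopifnot(inherits(sm, "spectral_matrix"))
  Xc <- preprocess(sm$values, spec, sm$grid)
  model <- pca_fit(Xc, n_components)
  rep <- detect_outliers(model, Xc, alpha, sample_ids = sm$sample_ids)
  keep <- !(sm$sample_ids %in% rep$flagged)
  kept <- sm_subset(sm, keep)
  Xc2 <- preprocess(kept$values, spec, kept$grid)
  list(kept = kept, report = rep,
       pca = pca_fit(Xc2, min(n_components, nrow(Xc2) - 1L)))
}
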