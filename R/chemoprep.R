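#' Labelled spectral matrix
#'
#' The object-wise modelling substrate: one mean spectrum per sample (rows)
#' by wavelength channel (columns), with class labels, sample ids and
#' treatment metadata.
#'
#' @param values samples x channels numeric matrix, no missing values.
#' @param grid [wavelength_grid()] matching the columns.
#' @param labels Class label per row (factor levels P1-P4 enforced when the
#'   labels are drawn from them).
#' @param sample_ids,treatments Optional per-row metadata.
#' @return A `spectral_matrix`.
#' @export
spectral_matrix <- function(values, grid, labels,
                            sample_ids = NULL, treatments = NULL) {
  values <- as.matrix(values)
  assert_wavelength_grid(grid)
  stopifnot(ncol(values) == length(grid$channels),
            nrow(values) == length(labels))
  if (anyNA(values)) stop("spectral matrix contains missing values",
                          call. = FALSE)
  labels <- if (all(labels %in% patty_categories()))
    factor(labels, levels = patty_categories()) else factor(labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(nrow(values)))
  colnames(values) <- sprintf("%.2f", grid$channels)
  rownames(values) <- sample_ids
  structure(list(values = values, grid = grid, labels = labels,
                 sample_ids = sample_ids,
                 treatments = treatments %||% rep(NA_character_, nrow(values))),
            class = "spectral_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d samples x %d channels\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.spectral_matrix <- function(x) dim(x$values)

# Subset rows of a spectral matrix, preserving metadata.
sm_subset <- function(sm, idx) {
  out <- sm
  out$values <- sm$values[idx, , drop = FALSE]
  out$labels <- sm$labels[idx]
  out$sample_ids <- sm$sample_ids[idx]
  out$treatments <- sm$treatments[idx]
  out
}

#' Column mean-centring
#'
#' Centres each channel to mean zero across samples and stores the column
#' means (attribute `"column_means"`) for reuse on new samples.
#'
#' @param X Numeric matrix (or `spectral_matrix` values), >= 2 rows.
#' @param means Optional precomputed column means (e.g. from the calibration
#'   set) to apply instead of the matrix's own.
#' @return Centred matrix with attribute `column_means`.
#' @export
mean_centre <- function(X, means = NULL) {
  X <- as.matrix(X)
  if (is.null(means)) {
    if (nrow(X) < 2) stop("mean-centring needs >= 2 samples", call. = FALSE)
    means <- colMeans(X)
  }
  out <- sweep(X, 2, means)
  attr(out, "column_means") <- means
  out
}

#' Standard normal variate (SNV)
#'
#' Centres and scales one spectrum to mean 0, sd 1, using the sample (n - 1)
#' standard deviation. Removes additive offsets and multiplicative scatter:
#' `snv(a * x + b) == snv(x)` for any `a > 0`.
#'
#' @param spectrum Numeric vector, >= 2 channels.
#' @return SNV-corrected spectrum.
#' @export
snv <- function(spectrum) {
  if (length(spectrum) < 2) stop("SNV needs >= 2 channels", call. = FALSE)
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s < .Machine$double.eps * max(1, abs(mean(spectrum))) * 10)
    stop("zero-variance spectrum: SNV undefined", call. = FALSE)
  (spectrum - mean(spectrum)) / s
}

#' Detrend a spectrum against wavelength
#'
#' Residual of the least-squares polynomial of the given order fitted to the
#' spectrum as a function of wavelength. Removes baseline shift (order 0
#' term) and curvature; with `order = 2` this is the classical companion to
#' SNV. Idempotent, and annihilates any polynomial of degree <= `order`.
#'
#' @param spectrum Numeric vector.
#' @param grid [wavelength_grid()] supplying the abscissa.
#' @param order Polynomial order (default 2); needs
#'   `length(spectrum) > order + 1`.
#' @return Detrended spectrum.
#' @export
detrend <- function(spectrum, grid = wavelength_grid(), order = 2) {
  if (order < 0) stop("`order` must be >= 0", call. = FALSE)
  n <- length(spectrum)
  if (n <= order + 1)
    stop("underdetermined detrend: need more channels than order + 1",
         call. = FALSE)
  lambda <- grid$channels[seq_len(n)]
  # scale abscissa for conditioning
  x <- (lambda - mean(lambda)) / (max(lambda) - min(lambda))
  B <- if (order == 0) NULL else stats::poly(x, degree = order, raw = FALSE)
  stats::lm.fit(cbind(1, B), spectrum)$residuals
}

#' Pre-processing specification
#'
#' @param method `"mean_centre"`, `"snv"` or `"snv_detrend"`.
#' @param detrend_order Polynomial order when `method = "snv_detrend"`.
#' @return A `preprocessing_spec`.
#' @export
preprocessing_spec <- function(method = c("snv", "snv_detrend", "mean_centre"),
                               detrend_order = 2) {
  method <- match.arg(method)
  if (method == "snv_detrend" && detrend_order < 1)
    stop("`detrend_order` must be >= 1 for snv_detrend", call. = FALSE)
  structure(list(method = method, detrend_order = detrend_order),
            class = "preprocessing_spec")
}

#' Pre-process a spectral matrix
#'
#' Applies the row-wise transform (SNV, or SNV followed by detrending)
#' and then centres columns across samples; `"mean_centre"` applies the
#' centring only. Row order and count are never altered. When `means` is
#' supplied (column means of a calibration set) those are applied, so
#' validation samples never influence the preprocessing statistics.
#'
#' @param X samples x channels matrix or `spectral_matrix` values.
#' @param spec [preprocessing_spec()].
#' @param grid Wavelength grid (needed for detrending).
#' @param means Optional calibration column means.
#' @param centre Apply the final column centring (default TRUE).
#' @return Processed matrix with attribute `column_means`.
#' @export
preprocess <- function(X, spec = preprocessing_spec(),
                       grid = wavelength_grid(), means = NULL,
                       centre = TRUE) {
  stopifnot(inherits(spec, "preprocessing_spec"))
  X <- as.matrix(X)
  if (spec$method %in% c("snv", "snv_detrend")) {
    for (i in seq_len(nrow(X))) {
      row <- tryCatch(snv(X[i, ]), error = function(e)
        stop(sprintf("row %d (%s): %s", i,
                     rownames(X)[i] %||% "unnamed", conditionMessage(e)),
             call. = FALSE))
      if (spec$method == "snv_detrend")
        row <- detrend(row, grid, spec$detrend_order)
      X[i, ] <- row
    }
  }
  if (centre) X <- mean_centre(X, means)
  X
}
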