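#' Scene geometry and noise specification for synthetic captures
#'
#' Describes one simulated capture: an elliptical patty on a dark silicone
#' tray. Spatial texture (slow compositional variation across the patty
#' surface), per-pixel multiplicative scatter, an additive polynomial
#' baseline in wavelength, and per-pixel detector noise are all configurable;
#' zeroing them yields an ideal capture whose every patty pixel carries the
#' pure mixture spectrum.
#'
#' @param image_rows,image_cols Image size in pixels (default 128 x 128).
#' @param ellipse_center Patty centre (row, col), 0-based pixel coordinates.
#' @param ellipse_axes Semi-axes (rows, cols) in pixels; the ellipse must fit
#'   inside the image.
#' @param background_absorbance Pseudo-absorbance of the tray (default 1.5,
#'   above the 1.1 segmentation threshold).
#' @param texture_correlation_length Correlation length (pixels) of the
#'   within-patty texture field.
#' @param texture_sd Relative sd of the texture field (default 0.03).
#' @param scatter_multiplier_sd Sd of the per-pixel multiplicative scatter
#'   factor (default 0.05).
#' @param baseline Additive polynomial baseline coefficients `c(b0, b1, b2)`
#'   applied on wavelength normalised to `[0, 1]`.
#' @param pixel_noise_sd Detector noise sd as a fraction of the local dynamic
#'   range W - D (default 0.005).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_rows = 128, image_cols = 128,
                       ellipse_center = c((image_rows - 1) / 2,
                                          (image_cols - 1) / 2),
                       ellipse_axes = c(0.35 * image_rows, 0.30 * image_cols),
                       background_absorbance = 1.5,
                       texture_correlation_length = 8,
                       texture_sd = 0.03,
                       scatter_multiplier_sd = 0.05,
                       baseline = c(0.02, 0.01, 0.005),
                       pixel_noise_sd = 0.005) {
  sc <- list(image_rows = as.integer(image_rows),
             image_cols = as.integer(image_cols),
             ellipse_center = ellipse_center,
             ellipse_axes = ellipse_axes,
             background_absorbance = background_absorbance,
             texture_correlation_length = texture_correlation_length,
             texture_sd = texture_sd,
             scatter_multiplier_sd = scatter_multiplier_sd,
             baseline = baseline,
             pixel_noise_sd = pixel_noise_sd)
  if (any(c(sc$texture_sd, sc$scatter_multiplier_sd, sc$pixel_noise_sd) < 0))
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (sc$ellipse_center[1] - sc$ellipse_axes[1] < 0 ||
      sc$ellipse_center[1] + sc$ellipse_axes[1] > sc$image_rows - 1 ||
      sc$ellipse_center[2] - sc$ellipse_axes[2] < 0 ||
      sc$ellipse_center[2] + sc$ellipse_axes[2] > sc$image_cols - 1)
    stop("ellipse must fit inside the image", call. = FALSE)
  if (sc$background_absorbance <= 1.1)
    stop("background absorbance must exceed the default segmentation ",
         "threshold (1.1)", call. = FALSE)
  structure(sc, class = "scene_spec")
}

# 0-based pixel-centre point-in-ellipse raster (rows x cols logical matrix)
ellipse_mask <- function(scene) {
  r <- seq_len(scene$image_rows) - 1
  c <- seq_len(scene$image_cols) - 1
  dr <- (r - scene$ellipse_center[1]) / scene$ellipse_axes[1]
  dc <- (c - scene$ellipse_center[2]) / scene$ellipse_axes[2]
  outer(dr^2, dc^2, `+`) <= 1
}

# Spatially correlated Gaussian field, unit variance, via FFT filtering of
# white noise with a Gaussian kernel of the given correlation length.
correlated_field <- function(nrow, ncol, corr_length) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (corr_length <= 0) return(z)
  fr <- c(0:(floor(nrow / 2)), -((ceiling(nrow / 2) - 1):1)) / nrow
  fc <- c(0:(floor(ncol / 2)), -((ceiling(ncol / 2) - 1):1)) / ncol
  # Gaussian kernel in Fourier space
  H <- exp(-2 * pi^2 * corr_length^2 * outer(fr^2, fc^2, `+`))
  f <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (nrow * ncol)
  s <- stats::sd(as.vector(f))
  if (s < .Machine$double.eps) return(matrix(0, nrow, ncol))
  f / s
}

#' Render the noise-free-optics scene as a pseudo-absorbance cube
#'
#' Patty pixels carry the pure mixture spectrum of `composition`, modulated
#' by (1 + texture) x (1 + scatter) where texture is a spatially correlated
#' field and scatter an i.i.d. per-pixel factor, plus an additive polynomial
#' baseline in normalised wavelength. Tray pixels carry the flat background
#' absorbance.
#'
#' @param scene A [scene_spec()].
#' @param composition Mass fractions (see [composition_for()]).
#' @param band_library Band library.
#' @param grid Wavelength grid.
#' @return List with `cube` (rows x cols x channels pseudo-absorbance array)
#'   and `mask` (ground-truth logical patty mask).
#' @export
render_true_scene <- function(scene, composition,
                              band_library = default_band_library(),
                              grid = wavelength_grid()) {
  stopifnot(inherits(scene, "scene_spec"))
  spectrum <- pure_mixture_spectrum(composition, band_library, grid)
  nr <- scene$image_rows; nc <- scene$image_cols
  npx <- nr * nc
  mask <- ellipse_mask(scene)

  pixfac <- rep(1, npx)
  if (scene$texture_sd > 0)
    pixfac <- pixfac * (1 + scene$texture_sd *
      as.vector(correlated_field(nr, nc, scene$texture_correlation_length)))
  if (scene$scatter_multiplier_sd > 0)
    pixfac <- pixfac * (1 + scene$scatter_multiplier_sd * stats::rnorm(npx))

  lam01 <- (grid$channels - grid$channels[1]) /
    (grid$channels[length(grid$channels)] - grid$channels[1])
  b <- scene$baseline
  baseline <- b[1] + b[2] * lam01 + b[3] * lam01^2

  # pixels x channels, then reshape
  A <- tcrossprod(pixfac, spectrum)
  A <- A + rep(baseline, each = npx)
  A[!as.vector(mask), ] <- scene$background_absorbance
  A[A < 0] <- 0
  list(cube = hypercube(array(A, dim = c(nr, nc, length(grid$channels))),
                        grid, unit = "pseudo_absorbance"),
       mask = mask)
}
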