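#' Hypercube container
#'
#' A rows x cols x channels array tagged with its wavelength grid and the
#' physical unit of its values.
#'
#' @param values 3-D numeric array (rows x cols x channels).
#' @param grid [wavelength_grid()] whose length matches the channel axis.
#' @param unit One of `"raw_irradiance"`, `"reflectance"`,
#'   `"pseudo_absorbance"`.
#' @return A `hypercube` object.
#' @export
hypercube <- function(values, grid,
                      unit = c("raw_irradiance", "reflectance",
                               "pseudo_absorbance")) {
  unit <- match.arg(unit)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  assert_wavelength_grid(grid)
  if (dim(values)[3] != length(grid$channels))
    stop("channel axis does not match the wavelength grid", call. = FALSE)
  structure(list(values = values, grid = grid, unit = unit),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d channels, unit: %s\n",
              d[1], d[2], d[3], x$unit))
  invisible(x)
}

#' Default smooth detector gain field
#'
#' Mild radial vignetting: gain 1 at the image centre falling to
#' `1 - falloff` in the corners. Shared by the dark, reference and sample
#' frames so that radiometric calibration cancels it.
#'
#' @param rows,cols Image size.
#' @param falloff Corner gain loss (default 0.15).
#' @return rows x cols matrix of positive gains.
#' @export
default_gain_field <- function(rows, cols, falloff = 0.15) {
  r <- (seq_len(rows) - (rows + 1) / 2) / (rows / 2)
  c <- (seq_len(cols) - (cols + 1) / 2) / (cols / 2)
  1 - falloff * outer(r^2, c^2, `+`) / 2
}

#' Simulate a raw capture from a true absorbance cube
#'
#' Applies the forward imaging model. The true reflectance is
#' `R_true = 10^(-A)`; the raw irradiance is
#' `R0 = D + (W - D) * R_true + noise`, where the dark frame `D` is a
#' constant offset and the reference frame `W = D + gain * illumination`
#' shares the detector gain field with the sample frame, so radiometric
#' calibration cancels the gain exactly. The grey reference tile is modelled
#' as the unit relative-reflectance target. With `noise_sd = 0`,
#' [correct_reflectance()] followed by [to_pseudo_absorbance()] recovers the
#' true absorbance cube to machine precision.
#'
#' @param true_cube `hypercube` in pseudo-absorbance units.
#' @param gain_field rows x cols positive gain matrix (default
#'   [default_gain_field()]).
#' @param dark_level Dark-frame irradiance offset (arbitrary counts).
#' @param illumination Full-scale irradiance above dark (counts).
#' @param noise_sd Per-pixel/channel Gaussian noise sd as a fraction of the
#'   local dynamic range `W - D`.
#' @param label,formulation Optional category label and formulation metadata
#'   carried on the capture.
#' @param references Optional precomputed `list(D, W)` reference cubes
#'   (reused across captures of one imaging session).
#' @return A `raw_capture`: list with `R0`, `D`, `W` (3-D arrays), `grid`,
#'   `label`, `formulation`.
#' @export
simulate_capture <- function(true_cube, gain_field = NULL, dark_level = 100,
                             illumination = 1000, noise_sd = 0.005,
                             label = NA_character_, formulation = NULL,
                             references = NULL) {
  stopifnot(inherits(true_cube, "hypercube"),
            true_cube$unit == "pseudo_absorbance", noise_sd >= 0)
  d <- dim(true_cube$values)
  if (is.null(gain_field)) gain_field <- default_gain_field(d[1], d[2])
  if (any(gain_field <= 0)) stop("gain field must be positive", call. = FALSE)

  if (is.null(references))
    references <- reference_frames(gain_field, dark_level, illumination, d[3])
  D <- references$D
  W <- references$W
  WD <- W - D

  R_true <- exp(-log(10) * true_cube$values)
  if (noise_sd > 0)
    R_true <- R_true + noise_sd * stats::rnorm(length(R_true))
  R0 <- D + WD * R_true

  structure(list(R0 = R0, D = D, W = W, grid = true_cube$grid,
                 label = label, formulation = formulation),
            class = "raw_capture")
}

# Dark and grey reference cubes for one imaging session (noise-free,
# idealised standards). W uses the grey tile as the unit-reflectance target.
reference_frames <- function(gain_field, dark_level, illumination, channels) {
  d <- c(dim(gain_field), channels)
  D <- array(dark_level, dim = d)
  W <- array(dark_level + as.vector(gain_field) * illumination, dim = d)
  list(D = D, W = W)
}

#' @export
print.raw_capture <- function(x, ...) {
  d <- dim(x$R0)
  cat(sprintf("<raw_capture> %s, %d x %d pixels, %d channels\n",
              ifelse(is.na(x$label), "unlabelled", x$label), d[1], d[2], d[3]))
  invisible(x)
}

#' Plan the captures of a synthetic study
#'
#' One row per capture: `n_per_category` patties per category, cycling the
#' category's treatments in order, with a per-capture child seed derived from
#' the root seed by a fixed counter scheme
#' (`(seed + 7919 * capture_index) mod (2^31 - 1)`), so captures can be
#' rendered independently and reproducibly in any order.
#'
#' @param n_per_category Captures per category (>= 1).
#' @param seed Root integer seed.
#' @return data.frame with `sample_id`, `category`, `treatment`,
#'   `capture_seed`.
#' @export
capture_plan <- function(n_per_category, seed = 42L) {
  if (n_per_category < 1) stop("`n_per_category` must be >= 1", call. = FALSE)
  form <- patty_formulations()
  rows <- do.call(rbind, lapply(patty_categories(), function(cat) {
    tr <- form$treatment[form$category == cat]
    data.frame(category = cat,
               treatment = tr[((seq_len(n_per_category) - 1) %% length(tr)) + 1])
  }))
  rows$sample_id <- sprintf("%s_%04d", rows$category,
                            as.integer(stats::ave(seq_len(nrow(rows)),
                                                  rows$category,
                                                  FUN = seq_along)))
  rows$capture_seed <- (as.numeric(seed) + 7919 * seq_len(nrow(rows))) %%
    (2^31 - 1)
  rows[, c("sample_id", "category", "treatment", "capture_seed")]
}

#' Render one planned capture
#'
#' Seeds the RNG with the plan row's child seed, draws the patty composition,
#' renders the scene and simulates the raw capture.
#'
#' @param plan_row One row of [capture_plan()].
#' @param scene [scene_spec()].
#' @param band_library Band library.
#' @param grid Wavelength grid.
#' @param jitter_sd,jitter_cor Compositional jitter (see [composition_for()]).
#' @param references Optional shared reference frames.
#' @return A `raw_capture` with `sample_id`, `treatment` and the drawn
#'   `composition` attached.
#' @export
render_capture <- function(plan_row, scene = scene_spec(),
                           band_library = default_band_library(),
                           grid = wavelength_grid(),
                           jitter_sd = 0.05, jitter_cor = 0.9,
                           references = NULL) {
  set.seed(as.integer(plan_row$capture_seed))
  comp <- composition_for(plan_row$category, plan_row$treatment,
                          jitter_sd = jitter_sd, jitter_cor = jitter_cor)
  truth <- render_true_scene(scene, comp, band_library, grid)
  cap <- simulate_capture(truth$cube, noise_sd = scene$pixel_noise_sd,
                          label = as.character(plan_row$category),
                          references = references)
  cap$sample_id <- plan_row$sample_id
  cap$treatment <- plan_row$treatment
  cap$composition <- comp
  cap$truth_mask <- truth$mask
  cap
}

#' Stream synthetic raw captures
#'
#' Returns an iterator over the planned study: each call to `$next_capture()`
#' renders and returns the next `raw_capture` (or `NULL` when exhausted), so
#' arbitrarily large studies run in bounded memory. Reference frames are
#' computed once and shared across the session, as reference standards are in
#' practice.
#'
#' @param n_per_category Captures per category.
#' @param scene [scene_spec()].
#' @param band_library Band library.
#' @param grid Wavelength grid.
#' @param jitter_sd,jitter_cor Compositional jitter parameters.
#' @param seed Root seed; the whole stream is reproducible from it.
#' @return A `capture_stream`: list with `plan` (the [capture_plan()]),
#'   `n` and functions `next_capture()` and `reset()`.
#' @export
generate_dataset <- function(n_per_category, scene = scene_spec(),
                             band_library = default_band_library(),
                             grid = wavelength_grid(),
                             jitter_sd = 0.05, jitter_cor = 0.9,
                             seed = 42L) {
  plan <- capture_plan(n_per_category, seed)
  refs <- reference_frames(
    default_gain_field(scene$image_rows, scene$image_cols),
    dark_level = 100, illumination = 1000,
    channels = length(grid$channels))
  i <- 0L
  structure(list(
    plan = plan,
    n = nrow(plan),
    next_capture = function() {
      if (i >= nrow(plan)) return(NULL)
      i <<- i + 1L
      render_capture(plan[i, ], scene, band_library, grid,
                     jitter_sd, jitter_cor, references = refs)
    },
    reset = function() i <<- 0L
  ), class = "capture_stream")
}

#' @export
print.capture_stream <- function(x, ...) {
  cat(sprintf("<capture_stream> %d captures (%d per category)\n",
              x$n, x$n / 4L))
  invisible(x)
}
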