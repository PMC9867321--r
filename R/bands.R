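#' Default NIR absorption band library for patty constituents
#'
#' Gaussian absorption bands per constituent, on the pseudo-absorbance scale
#' per unit mass fraction. The five dominant bands are the ones consistently
#' assigned in NIR spectra of processed meat: fat C-H stretch overtones at
#' 1198 and 1738 nm, water O-H bands at 1460 and 1934 nm, and the protein
#' CH2 combination band at 2326 nm. The carbohydrate filler (rusk/TVP starch
#' and fibre) absorbs through an O-H/C-O combination band near 2100 nm.
#' Secondary bands reported in PCA loadings of such data (1138, 1318, 1510,
#' 2294 nm) can be switched on but are off by default. All default widths are
#' sigma = 25 nm, giving the broad, partially resolved band shapes typical of
#' wet biological tissue; amplitudes are scaled so a typical patty spectrum
#' peaks around 0.9 pseudo-absorbance.
#'
#' @param include_secondary Add low-amplitude secondary bands (default FALSE).
#' @return A `band_library`: named list (moisture, fat, protein, filler) of
#'   data.frames with columns `center_nm`, `width_nm` (Gaussian sigma) and
#'   `amplitude` (pseudo-absorbance per unit mass fraction).
#' @export
default_band_library <- function(include_secondary = FALSE) {
  band <- function(center, width, amp)
    data.frame(center_nm = center, width_nm = width, amplitude = amp)
  lib <- list(
    moisture = band(c(1460, 1934), 25, c(0.80, 1.40)),
    fat      = band(c(1198, 1738), 25, c(1.20, 1.50)),
    protein  = band(2326, 25, 2.00),
    filler   = band(2100, 25, 1.60)
  )
  if (include_secondary) {
    lib$fat     <- rbind(lib$fat,     band(1138, 25, 0.15))
    lib$protein <- rbind(lib$protein, band(c(1318, 1510, 2294), 25,
                                           c(0.10, 0.10, 0.20)))
  }
  validate_band_library(lib)
}

validate_band_library <- function(lib) {
  stopifnot(is.list(lib), length(lib) >= 1)
  for (nm in names(lib)) {
    b <- lib[[nm]]
    if (nrow(b) < 1) stop("every constituent needs >= 1 band", call. = FALSE)
    if (any(b$width_nm <= 0)) stop("band widths must be > 0", call. = FALSE)
    if (any(b$amplitude < 0)) stop("band amplitudes must be >= 0", call. = FALSE)
  }
  structure(lib, class = "band_library")
}

#' Pure mixture pseudo-absorbance spectrum
#'
#' Beer-Lambert-style linear mixing: the spectrum is the sum over
#' constituents of (mass fraction) x (sum of that constituent's Gaussian
#' bands). Linear in the composition by construction.
#'
#' @param composition Named mass fractions; names must match the band library
#'   constituents (extra zero-fraction constituents allowed).
#' @param band_library A [default_band_library()]-shaped library.
#' @param grid A [wavelength_grid()].
#' @return Numeric pseudo-absorbance per grid channel (all values >= 0).
#' @export
#' Locate prominent absorption maxima in a spectrum
#'
#' Finds interior local maxima and their topographic prominence (height above
#' the higher of the two flanking saddles, walking outward until a higher
#' point or the spectrum edge).
#'
#' @param spectrum Numeric pseudo-absorbance vector.
#' @param grid Matching [wavelength_grid()].
#' @param min_prominence Keep maxima at least this prominent (default 0.02
#'   pseudo-absorbance).
#' @return data.frame: `channel`, `wavelength_nm`, `value`, `prominence`,
#'   ordered by wavelength.
#' @export
find_absorption_maxima <- function(spectrum, grid = wavelength_grid(),
                                   min_prominence = 0.02) {
  n <- length(spectrum)
  stopifnot(n >= 3, n <= length(grid$channels))
  peaks <- which(diff(sign(diff(spectrum))) == -2) + 1L
  prom <- vapply(peaks, function(i) {
    saddle <- function(idx) {
      run <- spectrum[idx]
      if (!length(run)) return(min(spectrum))
      higher <- which(run > spectrum[i])
      if (length(higher)) min(run[seq_len(higher[1])]) else min(run)
    }
    left <- saddle(rev(seq_len(i - 1L)))
    right <- saddle(seq(i + 1L, n))
    spectrum[i] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(channel = peaks[keep],
             wavelength_nm = grid$channels[peaks[keep]],
             value = spectrum[peaks[keep]],
             prominence = prom[keep])
}

pure_mixture_spectrum <- function(composition,
                                  band_library = default_band_library(),
                                  grid = wavelength_grid()) {
  assert_wavelength_grid(grid)
  lambda <- grid$channels
  if (!length(lambda)) stop("wavelength grid is empty", call. = FALSE)
  A <- numeric(length(lambda))
  for (constituent in names(band_library)) {
    frac <- composition[[constituent]]
    if (is.null(frac) || is.na(frac) || frac == 0) next
    b <- band_library[[constituent]]
    for (i in seq_len(nrow(b))) {
      A <- A + frac * b$amplitude[i] *
        exp(-(lambda - b$center_nm[i])^2 / (2 * b$width_nm[i]^2))
    }
  }
  A
}
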