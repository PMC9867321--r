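#' Construct a uniform wavelength grid
#'
#' Builds the ordered list of channel centre wavelengths for a push-broom
#' NIR-HSI instrument: `start_nm`, `start_nm + step_nm`, ... up to the largest
#' value not exceeding `max_nm`. The package default mirrors a SWIR camera
#' sampling 952-2517 nm in 5.45 nm increments, which yields 288 channels.
#'
#' @param start_nm First channel centre (nm).
#' @param step_nm Channel increment (nm); must be positive.
#' @param max_nm Upper wavelength bound (nm); must exceed `start_nm`.
#' @return An object of class `wavelength_grid`: a list with `start_nm`,
#'   `step_nm` and `channels` (numeric vector of centre wavelengths, nm).
#' @examples
#' g <- wavelength_grid()
#' length(g$channels)  # 288
#' @export
wavelength_grid <- function(start_nm = 952, step_nm = 5.45, max_nm = 2517) {
  if (!is.numeric(step_nm) || length(step_nm) != 1L || step_nm <= 0)
    stop("`step_nm` must be a single positive number", call. = FALSE)
  if (max_nm <= start_nm)
    stop("`max_nm` must exceed `start_nm`", call. = FALSE)
  n <- floor((max_nm - start_nm) / step_nm) + 1L
  channels <- start_nm + step_nm * (seq_len(n) - 1)
  structure(
    list(start_nm = start_nm, step_nm = step_nm, channels = channels),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d channels, %.2f-%.2f nm, step %.2f nm\n",
              length(x$channels), x$channels[1],
              x$channels[length(x$channels)], x$step_nm))
  invisible(x)
}

#' @export
length.wavelength_grid <- function(x) length(x$channels)

#' Index of the channel nearest a target wavelength
#'
#' Ties (a target exactly midway between two channels) resolve to the lower
#' channel.
#'
#' @param grid A [wavelength_grid()].
#' @param nm Target wavelength (nm); must lie within the grid range.
#' @return Integer channel index.
#' @export
nearest_channel <- function(grid, nm) {
  ch <- grid$channels
  if (nm < ch[1] || nm > ch[length(ch)])
    stop(sprintf("wavelength %.2f nm outside grid range [%.2f, %.2f]",
                 nm, ch[1], ch[length(ch)]), call. = FALSE)
  d <- abs(ch - nm)
  which(d <= min(d) + 1e-12)[1L]
}

assert_wavelength_grid <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  d <- diff(grid$channels)
  if (length(d) && (any(d <= 0) || max(abs(d - grid$step_nm)) > 1e-9))
    stop("wavelength grid must be strictly increasing with uniform spacing",
         call. = FALSE)
  invisible(grid)
}
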