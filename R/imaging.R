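#' Radiometric calibration of a raw capture
#'
#' Converts raw irradiance to relative reflectance against the dark (0%
#' reflectance) and grey reference frames:
#' `R = (R0 - D) / (W - D)`, elementwise per pixel and channel. The shared
#' illumination/gain structure of the frames cancels, so the result is
#' invariant to any positive multiplicative illumination field common to the
#' three frames.
#'
#' @param capture A `raw_capture` (see [simulate_capture()]).
#' @return `hypercube` in reflectance units.
#' @export
correct_reflectance <- function(capture) {
  stopifnot(inherits(capture, "raw_capture"))
  WD <- capture$W - capture$D
  if (min(WD) <= 0) {
    d <- dim(capture$W)
    idx <- arrayInd(which(WD <= 0)[1L], d)
    stop(sprintf(paste0("degenerate reference: W == D at pixel (%d, %d), ",
                        "channel %d"), idx[1], idx[2], idx[3]), call. = FALSE)
  }
  hypercube((capture$R0 - capture$D) / WD, capture$grid, unit = "reflectance")
}

#' Convert reflectance to pseudo-absorbance
#'
#' `A = log10(1 / max(R, floor))`. The floor guards against non-positive
#' reflectance produced by detector noise in dark regions.
#'
#' @param cube Reflectance `hypercube`.
#' @param floor Smallest reflectance admitted before the log (default 1e-6).
#' @return `hypercube` in pseudo-absorbance units.
#' @export
to_pseudo_absorbance <- function(cube, floor = 1e-6) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$unit != "reflectance")
    stop("input must be in reflectance units", call. = FALSE)
  if (floor <= 0) stop("`floor` must be > 0", call. = FALSE)
  v <- cube$values
  if (min(v) < floor) v[v < floor] <- floor
  hypercube(-log(v) / log(10), cube$grid, unit = "pseudo_absorbance")
}

#' Segmentation parameters
#'
#' Threshold rule for separating the patty from the dark tray. Foreground is
#' by default the set of pixels whose pseudo-absorbance at the channel
#' nearest `band_nm` falls *below* the threshold: the black silicone tray
#' absorbs more than the patty. `foreground_below = FALSE` flips the rule for
#' bright-background set-ups.
#'
#' @param band_nm Segmentation wavelength (default 952 nm).
#' @param threshold Pseudo-absorbance cut (default 1.1).
#' @param connectivity Pixel connectivity for component cleaning, 4 or 8.
#' @param min_object_pixels Components smaller than this are always dropped.
#' @param foreground_below Logical; see above.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(band_nm = 952, threshold = 1.1,
                                connectivity = 8, min_object_pixels = 50,
                                foreground_below = TRUE) {
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  structure(list(band_nm = band_nm, threshold = threshold,
                 connectivity = connectivity,
                 min_object_pixels = min_object_pixels,
                 foreground_below = foreground_below),
            class = "segmentation_params")
}

#' Threshold a pseudo-absorbance cube into a binary mask
#'
#' Selects the channel nearest `params$band_nm` and marks each pixel 1
#' (object/ROI) or 0 (background) by the threshold rule.
#'
#' @param cube Pseudo-absorbance `hypercube`.
#' @param params [segmentation_params()].
#' @return `binary_mask`: list with integer `values` matrix in `{0, 1}` and
#'   the `provenance` parameters used.
#' @export
threshold_mask <- function(cube, params = segmentation_params()) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$unit != "pseudo_absorbance")
    stop("segmentation expects pseudo-absorbance input", call. = FALSE)
  ch <- nearest_channel(cube$grid, params$band_nm)
  plane <- cube$values[, , ch]
  m <- if (params$foreground_below) plane < params$threshold
       else plane > params$threshold
  binary_mask(m * 1L, provenance = params)
}

binary_mask <- function(values, provenance = NULL) {
  stopifnot(is.matrix(values), all(values %in% c(0L, 1L)))
  structure(list(values = matrix(as.integer(values), nrow(values)),
                 provenance = provenance), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d object pixels\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

# Connected-component labelling via run-length encoding per column and
# union-find over runs (classic two-pass CCL; supports 4- and 8-connectivity).
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask != 0L
  nr <- nrow(m); nc <- ncol(m)
  # vertical runs of object pixels per column
  runs <- list(); col_runs <- vector("list", nc)
  for (j in seq_len(nc)) {
    v <- m[, j]
    if (!any(v)) { col_runs[[j]] <- integer(); next }
    d <- diff(c(0L, v, 0L))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    ids <- length(runs) + seq_along(starts)
    runs[ids] <- Map(function(s, e) c(j, s, e), starts, ends)
    col_runs[[j]] <- ids
  }
  n_runs <- length(runs)
  if (n_runs == 0) return(matrix(0L, nr, nc))
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  for (j in 2:max(2L, nc)) {
    if (j > nc) break
    for (a in col_runs[[j]]) {
      ra <- runs[[a]]
      for (b in col_runs[[j - 1L]]) {
        rb <- runs[[b]]
        if (rb[2] <= ra[3] + slack && rb[3] >= ra[2] - slack) {
          fa <- find(a); fb <- find(b)
          if (fa != fb) parent[max(fa, fb)] <- min(fa, fb)
        }
      }
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  lab_of_run <- as.integer(factor(roots, levels = unique(roots[order(roots)])))
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(n_runs)) {
    r <- runs[[i]]
    lab[r[2]:r[3], r[1]] <- lab_of_run[i]
  }
  lab
}

#' Clean a binary mask
#'
#' Labels connected components under the requested connectivity, drops every
#' component smaller than `min_object_pixels`, and retains only the largest
#' remaining component (ties broken by smallest label, i.e. top-left-most
#' seed). Idempotent.
#'
#' @param mask `binary_mask` or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @param min_object_pixels Minimum component size.
#' @return Cleaned `binary_mask`.
#' @export
clean_mask <- function(mask, connectivity = 8, min_object_pixels = 50) {
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  if (sum(v) == 0)
    stop("empty segmentation: mask contains no object pixels", call. = FALSE)
  lab <- label_components(v, connectivity)
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < min_object_pixels] <- 0L
  if (all(sizes == 0))
    stop("empty segmentation: no component reaches `min_object_pixels`",
         call. = FALSE)
  keep <- which.max(sizes)
  binary_mask((lab == keep) * 1L,
              provenance = list(connectivity = connectivity,
                                min_object_pixels = min_object_pixels))
}

#' Apply a binary mask to a hypercube
#'
#' Masked-out pixels are set to `NA` (a sentinel excluded from all
#' statistics); object pixels are unchanged.
#'
#' @param cube `hypercube`.
#' @param mask `binary_mask` or 0/1 matrix with matching rows x cols.
#' @return Masked `hypercube`.
#' @export
apply_mask <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  d <- dim(cube$values)
  if (!all(dim(v) == d[1:2]))
    stop("mask shape does not match the cube", call. = FALSE)
  out <- cube$values
  out[array(v == 0L, dim = d)] <- NA_real_
  hypercube(out, cube$grid, unit = cube$unit)
}

#' Object-wise mean spectrum
#'
#' Per-channel arithmetic mean over object pixels only.
#'
#' @param cube `hypercube`.
#' @param mask `binary_mask` or 0/1 matrix; must contain at least one object
#'   pixel. `NULL` averages all non-`NA` pixels (e.g. after [apply_mask()]).
#' @return Numeric vector, one mean per channel.
#' @export
mean_spectrum <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  X <- matrix(cube$values, d[1] * d[2], d[3])
  if (!is.null(mask)) {
    v <- if (inherits(mask, "binary_mask")) mask$values else mask
    if (!all(dim(v) == d[1:2]))
      stop("mask shape does not match the cube", call. = FALSE)
    if (sum(v) == 0) stop("mask has no object pixels", call. = FALSE)
    X <- X[as.vector(v == 1L), , drop = FALSE]
  }
  out <- colMeans(X, na.rm = TRUE)
  if (anyNA(out)) stop("no valid pixels to average", call. = FALSE)
  out
}

# One capture through the calibrate -> absorbance -> threshold -> clean ->
# mean chain. Identical in result to composing the exported operations (a
# test asserts this), but calibrates only the segmentation plane and the
# masked pixels, which is what dominates the cost of large studies.
extract_one <- function(cap, params = segmentation_params(), floor = 1e-6) {
  d <- dim(cap$R0)
  npx <- d[1] * d[2]
  WD <- cap$W - cap$D
  if (min(WD) <= 0) {
    idx <- arrayInd(which(WD <= 0)[1L], d)
    stop(sprintf(paste0("degenerate reference: W == D at pixel (%d, %d), ",
                        "channel %d"), idx[1], idx[2], idx[3]), call. = FALSE)
  }
  ch <- nearest_channel(cap$grid, params$band_nm)
  plane <- (cap$R0[, , ch] - cap$D[, , ch]) / WD[, , ch]
  plane[plane < floor] <- floor
  planeA <- -log(plane) / log(10)
  m <- if (params$foreground_below) planeA < params$threshold
       else planeA > params$threshold
  mask <- clean_mask(binary_mask(m * 1L, provenance = params),
                     params$connectivity, params$min_object_pixels)
  idx <- which(mask$values == 1L)
  as_px <- function(a) { dim(a) <- c(npx, d[3]); a[idx, , drop = FALSE] }
  R <- (as_px(cap$R0) - as_px(cap$D)) / as_px(WD)
  R[R < floor] <- floor
  colMeans(-log(R) / log(10))
}

#' Extract the object-wise spectral matrix from a set of captures
#'
#' Runs the full per-capture chain -- radiometric calibration,
#' pseudo-absorbance conversion, threshold segmentation, component cleaning,
#' mean-spectrum calculation -- and stacks one row per capture, in input
#' order, into a labelled spectral matrix. Per-capture segmentation failures
#' are collected (with the capture identity) rather than aborting the run;
#' failed captures are excluded from the matrix.
#'
#' @param captures A `capture_stream` from [generate_dataset()], or a list of
#'   `raw_capture` objects.
#' @param params [segmentation_params()].
#' @param floor Reflectance floor for the log transform.
#' @return A `spectral_matrix` (see [spectral_matrix()]); attribute
#'   `failures` lists capture ids that could not be segmented.
#' @export
extract_matrix <- function(captures, params = segmentation_params(),
                           floor = 1e-6) {
  nxt <- if (inherits(captures, "capture_stream")) {
    captures$reset()
    captures$next_capture
  } else {
    stopifnot(is.list(captures), length(captures) >= 1)
    i <- 0L
    function() {
      if (i >= length(captures)) return(NULL)
      i <<- i + 1L
      captures[[i]]
    }
  }
  rows <- list(); ids <- character(); labs <- character()
  treats <- character(); failures <- character()
  grid <- NULL
  repeat {
    cap <- nxt()
    if (is.null(cap)) break
    grid <- cap$grid
    id <- if (!is.null(cap$sample_id)) cap$sample_id
          else sprintf("capture_%04d", length(ids) + length(failures) + 1L)
    spec <- tryCatch(extract_one(cap, params, floor), error = function(e) e)
    if (inherits(spec, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(spec)))
      next
    }
    rows[[length(rows) + 1L]] <- spec
    ids <- c(ids, id)
    labs <- c(labs, as.character(cap$label))
    treats <- c(treats, if (is.null(cap$treatment)) NA_character_
                        else cap$treatment)
  }
  if (!length(rows))
    stop("no capture could be segmented", call. = FALSE)
  sm <- spectral_matrix(do.call(rbind, rows), grid, labels = labs,
                        sample_ids = ids, treatments = treats)
  attr(sm, "failures") <- failures
  sm
}
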