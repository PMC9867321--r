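# Minimal ENVI hypercube I/O: a plain-text .hdr describing a raw binary
# data file. Writing uses 32-bit little-endian float, BIL interleave, with
# the wavelength list carried in the header; reading supports BIL, BSQ and
# BIP interleaves (data types 4 = float32 and 5 = float64).

#' Write a hypercube as an ENVI image
#'
#' @param cube A `hypercube`.
#' @param path Output path without extension; writes `<path>.img` and
#'   `<path>.hdr`.
#' @param interleave `"bil"`, `"bsq"` or `"bip"`.
#' @return Invisibly, the two paths written.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$values)  # rows (lines) x cols (samples) x bands
  img <- paste0(path, ".img"); hdr <- paste0(path, ".hdr")
  # reorder to the requested interleave; R arrays are column-major
  v <- cube$values
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # samples, lines, bands
                 bil = c(2, 3, 1),   # samples, bands, lines
                 bip = c(3, 2, 1))   # bands, samples, lines
  con <- file(img, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(v, perm)), con, size = 4, endian = "little")
  header <- c(
    "ENVI",
    "description = {synthetic NIR-HSI capture}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength units = Nanometers"),
    sprintf("unit = %s", cube$unit),
    sprintf("wavelength = {%s}",
            paste(format(cube$grid$channels, trim = TRUE), collapse = ", "))
  )
  writeLines(header, hdr)
  invisible(c(img = img, hdr = hdr))
}

parse_envi_header <- function(hdr) {
  txt <- paste(readLines(hdr, warn = FALSE), collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("(?mi)^%s\\s*=\\s*([^\\n{]+)", key),
                                 txt, perl = TRUE))
    if (!length(m)) return(NA_character_)
    trimws(sub(sprintf("(?i)^%s\\s*=\\s*", key), "", m, perl = TRUE))
  }
  braced <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("(?si)%s\\s*=\\s*\\{([^}]*)\\}", key),
                                 txt, perl = TRUE))
    if (!length(m)) return(NULL)
    inner <- sub("^[^{]*\\{", "", m); inner <- sub("\\}$", "", inner)
    as.numeric(strsplit(inner, ",")[[1]])
  }
  list(samples = as.integer(get1("samples")),
       lines = as.integer(get1("lines")),
       bands = as.integer(get1("bands")),
       data_type = as.integer(get1("data type")),
       interleave = tolower(get1("interleave")),
       byte_order = as.integer(get1("byte order")),
       unit = get1("unit"),
       wavelength = braced("wavelength"))
}

#' Read an ENVI image as a hypercube
#'
#' @param path Path to the `.hdr` or the data file (the sibling is inferred).
#' @param unit Unit tag override; defaults to the `unit` header field or
#'   `"raw_irradiance"`.
#' @return A `hypercube`.
#' @export
read_envi <- function(path, unit = NULL) {
  hdr <- if (grepl("\\.hdr$", path)) path else paste0(sub("\\.img$", "", path),
                                                      ".hdr")
  img <- sub("\\.hdr$", ".img", hdr)
  if (!file.exists(hdr)) stop(sprintf("missing ENVI header: %s", hdr),
                              call. = FALSE)
  if (!file.exists(img)) stop(sprintf("missing ENVI data file: %s", img),
                              call. = FALSE)
  h <- parse_envi_header(hdr)
  if (!h$data_type %in% c(4L, 5L))
    stop("only ENVI data types 4 (float32) and 5 (float64) are supported",
         call. = FALSE)
  size <- if (h$data_type == 4L) 4L else 8L
  endian <- if (identical(h$byte_order, 1L)) "big" else "little"
  n <- h$samples * h$lines * h$bands
  raw <- readBin(img, what = "numeric", n = n, size = size, endian = endian)
  if (length(raw) != n) stop("ENVI data file truncated", call. = FALSE)
  dims <- switch(h$interleave,
                 bsq = c(h$samples, h$lines, h$bands),
                 bil = c(h$samples, h$bands, h$lines),
                 bip = c(h$bands, h$samples, h$lines),
                 stop("unknown interleave", call. = FALSE))
  arr <- array(raw, dim = dims)
  inv <- switch(h$interleave,
                bsq = c(2, 1, 3),
                bil = c(3, 1, 2),
                bip = c(3, 2, 1))
  v <- aperm(arr, inv)
  if (is.null(h$wavelength) || length(h$wavelength) != h$bands)
    stop("ENVI header lacks a usable wavelength list", call. = FALSE)
  step <- mean(diff(h$wavelength))
  grid <- wavelength_grid(h$wavelength[1], step,
                          h$wavelength[h$bands] + step / 2)
  unit <- unit %||% (if (!is.na(h$unit)) h$unit else "raw_irradiance")
  hypercube(v, grid, unit = unit)
}
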