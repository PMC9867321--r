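# Shared fixtures and independent brute-force oracles.

# short wavelength grid for model/statistics tests that do not need 288
# channels
small_grid <- function(n_channels = 20, start = 1000, step = 10) {
  wavelength_grid(start, step, start + step * (n_channels - 1) + step / 2)
}

# a small scene that renders quickly
small_scene <- function(...) {
  scene_spec(image_rows = 48, image_cols = 48, ...)
}

# scene with every stochastic/optical artifact disabled
noiseless_scene <- function(rows = 48, cols = 48) {
  scene_spec(image_rows = rows, image_cols = cols,
             texture_sd = 0, scatter_multiplier_sd = 0,
             baseline = c(0, 0, 0), pixel_noise_sd = 0)
}

# labelled spectral matrix with class structure on a few channels:
# class k has mean mu * k on channel 1, noise everywhere
toy_spectral_matrix <- function(n_per_class = 15, n_channels = 12,
                                mu = 5, noise = 0.5, seed = 11,
                                classes = patty_categories()) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  X <- matrix(rnorm(n * n_channels, sd = noise), n, n_channels)
  labels <- rep(classes, each = n_per_class)
  for (k in seq_along(classes)) {
    rows <- which(labels == classes[k])
    X[rows, 1] <- X[rows, 1] + mu * k
    X[rows, 2] <- X[rows, 2] - mu * k / 2
  }
  spectral_matrix(X, small_grid(n_channels), labels = labels)
}

# brute-force flood fill labelling (queue-based), the oracle for
# label_components / clean_mask
flood_fill_labels <- function(mask, connectivity = 8) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      (\(d) Map(c, d$dr, d$dc)[!(d$dr == 0 & d$dc == 0)])()
  }
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      px <- queue[1]; queue <- queue[-1]
      r <- (px - 1L) %% nr + 1L
      c <- (px - 1L) %/% nr + 1L
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, (cc - 1L) * nr + rr)
        }
      }
    }
  }
  lab
}

# brute-force point-in-ellipse raster count
ellipse_area_bruteforce <- function(scene) {
  count <- 0L
  for (r in 0:(scene$image_rows - 1)) {
    for (c in 0:(scene$image_cols - 1)) {
      if (((r - scene$ellipse_center[1]) / scene$ellipse_axes[1])^2 +
          ((c - scene$ellipse_center[2]) / scene$ellipse_axes[2])^2 <= 1)
        count <- count + 1L
    }
  }
  count
}
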