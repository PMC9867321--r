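# Radiometric calibration, segmentation, masking, mean-spectrum extraction.

make_capture <- function(R0, D, W, grid) {
  structure(list(R0 = R0, D = D, W = W, grid = grid, label = "P1"),
            class = "raw_capture")
}

test_that("reflectance calibration is exact on dark, reference and linear
           mixes, and reports degenerate references", {
  g <- small_grid(4)
  d <- c(3, 3, 4)
  D <- array(100, d); W <- array(600, d)
  expect_equal(correct_reflectance(make_capture(D, D, W, g))$values,
               array(0, d))
  expect_equal(correct_reflectance(make_capture(W, D, W, g))$values,
               array(1, d))
  mix <- D + 0.25 * (W - D)
  expect_equal(correct_reflectance(make_capture(mix, D, W, g))$values,
               array(0.25, d))
  Wbad <- W; Wbad[2, 3, 1] <- 100
  expect_error(correct_reflectance(make_capture(D, D, Wbad, g)),
               "pixel \\(2, 3\\), channel 1")
})

test_that("pseudo-absorbance conversion applies log10(1/R) with a floor", {
  g <- small_grid(3)
  mk <- function(r) hypercube(array(r, dim = c(2, 2, 3)), g, "reflectance")
  expect_equal(to_pseudo_absorbance(mk(1))$values, array(0, c(2, 2, 3)))
  expect_equal(to_pseudo_absorbance(mk(0.1))$values, array(1, c(2, 2, 3)),
               tolerance = 1e-12)
  expect_equal(to_pseudo_absorbance(mk(0), floor = 1e-6)$values,
               array(6, c(2, 2, 3)))
  cube_abs <- hypercube(array(1, c(2, 2, 3)), g, "pseudo_absorbance")
  expect_error(to_pseudo_absorbance(cube_abs), "reflectance")
})

test_that("threshold segmentation recovers the ground-truth ellipse and
           defaults to the documented rule", {
  p <- segmentation_params()
  expect_equal(p$band_nm, 952)
  expect_equal(p$threshold, 1.1)

  g <- small_grid(3)
  uniform <- hypercube(array(1.5, c(6, 6, 3)), g, "pseudo_absorbance")
  expect_identical(sum(threshold_mask(uniform,
                                      segmentation_params(band_nm = 1000)
                                      )$values), 0L)

  sc <- noiseless_scene()
  out <- render_true_scene(sc, composition_for("P1", jitter_sd = 0))
  m <- threshold_mask(out$cube, segmentation_params(band_nm = 1000))
  expect_identical(m$values, matrix(as.integer(out$mask), 48, 48))
  expect_identical(sum(m$values), ellipse_area_bruteforce(sc))
})

test_that("mask cleaning keeps the largest component, is idempotent and
           matches a brute-force flood fill", {
  m <- matrix(0L, 40, 40)
  m[2:21, 2:21] <- 1L          # 400 px blob
  m[30:32, 30:32] <- 0L; m[30:31, 35:37] <- 1L  # 6 px blob
  cleaned <- clean_mask(m, connectivity = 8, min_object_pixels = 50)
  expect_identical(sum(cleaned$values), 400L)
  expect_identical(clean_mask(cleaned, 8, 50)$values, cleaned$values)
  expect_error(clean_mask(matrix(0L, 5, 5)), "empty segmentation")
  expect_error(clean_mask(m, 8, min_object_pixels = 1000),
               "empty segmentation")

  set.seed(77)
  for (conn in c(4, 8)) {
    for (rep in 1:5) {
      rnd <- matrix(rbinom(30 * 30, 1, 0.4), 30, 30)
      if (sum(rnd) == 0) next
      ours <- pattyHSI:::label_components(rnd, conn)
      oracle <- flood_fill_labels(rnd, conn)
      # same partition: label images agree up to renaming
      expect_identical(max(ours), max(oracle))
      expect_true(all(tapply(oracle[rnd == 1], ours[rnd == 1],
                             function(x) length(unique(x))) == 1))
      # cleaning keeps exactly the largest oracle component
      sizes <- tabulate(oracle[oracle > 0])
      if (max(sizes) >= 5) {
        kept <- clean_mask(rnd, conn, min_object_pixels = 5)
        expect_identical(sum(kept$values), max(sizes))
      }
    }
  }
})

test_that("apply_mask excludes exactly the masked pixels", {
  g <- small_grid(3)
  set.seed(8)
  cube <- hypercube(array(runif(6 * 6 * 3), c(6, 6, 3)), g, "reflectance")
  ones <- matrix(1L, 6, 6)
  expect_equal(apply_mask(cube, ones)$values, cube$values)
  zero <- matrix(0L, 6, 6)
  expect_true(all(is.na(apply_mask(cube, zero)$values)))
  checker <- (outer(1:6, 1:6, `+`) %% 2L)
  masked <- apply_mask(cube, checker)
  expect_identical(sum(!is.na(masked$values[, , 1])), 18L)
  expect_error(apply_mask(cube, matrix(1L, 3, 3)), "shape")
})

test_that("mean_spectrum equals the brute-force per-channel loop", {
  g <- small_grid(3)
  vals <- array(0, c(2, 1, 3)); vals[1, 1, ] <- 0; vals[2, 1, ] <- 1
  cube <- hypercube(vals, g, "pseudo_absorbance")
  expect_equal(mean_spectrum(cube, matrix(1L, 2, 1)), c(0.5, 0.5, 0.5),
               ignore_attr = TRUE)
  uni <- hypercube(array(3.25, c(4, 4, 3)), g, "pseudo_absorbance")
  expect_equal(mean_spectrum(uni, matrix(1L, 4, 4)), rep(3.25, 3),
               ignore_attr = TRUE)

  set.seed(21)
  for (rep in 1:5) {
    cube <- hypercube(array(rnorm(5 * 5 * 3), c(5, 5, 3)), g,
                      "pseudo_absorbance")
    mask <- matrix(rbinom(25, 1, 0.5), 5, 5)
    if (sum(mask) == 0) mask[3, 3] <- 1L
    oracle <- numeric(3)
    for (ch in 1:3) {
      tot <- 0; cnt <- 0
      for (r in 1:5) for (c in 1:5) if (mask[r, c] == 1) {
        tot <- tot + cube$values[r, c, ch]; cnt <- cnt + 1
      }
      oracle[ch] <- tot / cnt
    }
    expect_equal(unname(mean_spectrum(cube, mask)), oracle,
                 tolerance = 1e-12)
  }
  expect_error(mean_spectrum(uni, matrix(0L, 4, 4)), "object pixels")
})

test_that("extract_matrix runs the documented chain: one row per capture,
           matching the composed operations and the pure spectrum", {
  plan <- capture_plan(1, seed = 3L)
  sc <- noiseless_scene()
  cap <- render_capture(plan[1, ], sc, jitter_sd = 0)
  sm <- extract_matrix(list(cap))
  expect_identical(dim(sm$values), c(1L, 288L))
  expect_identical(as.character(sm$labels), "P1")

  # noiseless, texture-free capture reproduces the pure mixture spectrum
  comp <- composition_for("P1", plan$treatment[1], jitter_sd = 0)
  expect_equal(unname(sm$values[1, ]), pure_mixture_spectrum(comp),
               tolerance = 1e-6)

  # the optimised path is exactly the composition of the exported operations
  A <- to_pseudo_absorbance(correct_reflectance(cap))
  mask <- clean_mask(threshold_mask(A), 8, 50)
  expect_identical(unname(sm$values[1, ]), unname(mean_spectrum(A, mask)))

  # failure isolation: an unsegmentable capture is excluded, not fatal
  bad <- cap
  bad$R0 <- cap$D  # dark frame: absorbance at the floor everywhere
  bad$sample_id <- "broken"
  sc2 <- extract_matrix(list(cap, bad))
  expect_identical(nrow(sc2$values), 1L)
  expect_match(attr(sc2, "failures"), "broken")
})
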