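# Synthetic capture generator: compositions, mixture spectra, scene
# rendering and the forward imaging model.

test_that("category compositions reproduce the published proximate means", {
  cm <- category_composition_means()
  expect_equal(unname(cm["P1", "protein"]), 0.195)
  expect_equal(unname(cm["P4", "protein"]), 0.104)
  expect_equal(unname(cm["P2", "moisture"]), 0.650)
  expect_equal(unname(cm["P3", "fat"]), 0.116)
  # treatment offsets cancel across a category's treatments
  form <- patty_formulations()
  for (cat in patty_categories()) {
    treats <- form$treatment[form$category == cat]
    profs <- sapply(treats, function(tr)
      composition_for(cat, tr, jitter_sd = 0))
    expect_equal(rowMeans(profs), cm[cat, ], tolerance = 1e-12)
    # every treatment stays within one absolute percentage point of the mean
    expect_true(all(abs(profs - cm[cat, ]) <= 0.01 + 1e-12))
  }
  expect_error(composition_for("P9"), "unknown")
})

test_that("zero-jitter compositions are deterministic; jittered draws are
           unbiased within Monte Carlo error", {
  a <- composition_for("P2", "pork_1", jitter_sd = 0)
  b <- composition_for("P2", "pork_1", jitter_sd = 0)
  expect_identical(a, b)

  set.seed(404)
  n <- 500
  cm <- category_composition_means()
  for (cat in patty_categories()) {
    draws <- replicate(n, composition_for(cat, jitter_sd = 0.05))
    for (k in rownames(draws)) {
      if (cm[cat, k] == 0) next
      se <- sd(draws[k, ]) / sqrt(n)
      expect_lt(abs(mean(draws[k, ]) - cm[cat, k]), 3 * se + 1e-12)
    }
  }
})

test_that("mixture spectra are linear in composition with the documented
           band structure", {
  g <- wavelength_grid()
  zero <- c(moisture = 0, fat = 0, protein = 0, filler = 0)
  expect_equal(pure_mixture_spectrum(zero, grid = g), numeric(288))

  comp <- composition_for("P1", jitter_sd = 0)
  s1 <- pure_mixture_spectrum(comp, grid = g)
  s2 <- pure_mixture_spectrum(comp * 2, grid = g)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_true(all(s1 >= 0))

  # oracle: evaluate the Gaussian-sum closed form independently and take the
  # argmax; the dominant water band sits at 1934 nm
  lib <- default_band_library()
  oracle <- numeric(288)
  for (con in names(lib)) {
    for (i in seq_len(nrow(lib[[con]]))) {
      b <- lib[[con]][i, ]
      oracle <- oracle + comp[[con]] * b$amplitude *
        exp(-(g$channels - b$center_nm)^2 / (2 * b$width_nm^2))
    }
  }
  expect_equal(s1, oracle, tolerance = 1e-12)
  expect_identical(which.max(s1), nearest_channel(g, 1934))
})

test_that("scene rendering separates patty and background as specified", {
  sc <- noiseless_scene()
  comp <- composition_for("P3", jitter_sd = 0)
  out <- render_true_scene(sc, comp)
  spectrum <- pure_mixture_spectrum(comp)
  inside <- which(out$mask)
  v <- matrix(out$cube$values, 48 * 48, 288)
  expect_equal(v[inside[1], ], spectrum, tolerance = 1e-12)
  expect_equal(max(abs(sweep(v[inside, ], 2, spectrum))), 0)
  outside <- which(!out$mask)
  expect_true(all(v[outside, ] == sc$background_absorbance))
  expect_identical(sum(out$mask), ellipse_area_bruteforce(sc))
})

test_that("the forward model reproduces the reference frames at the
           reflectance extremes", {
  g <- small_grid(5)
  mk <- function(a) hypercube(array(a, dim = c(4, 4, 5)), g,
                              unit = "pseudo_absorbance")
  capW <- simulate_capture(mk(0), noise_sd = 0)
  expect_equal(capW$R0, capW$W, tolerance = 1e-12)
  capD <- simulate_capture(mk(40), noise_sd = 0)   # R_true ~ 10^-40
  expect_equal(capD$R0, capD$D, tolerance = 1e-9)
})

test_that("noiseless capture round-trips through calibration to the true
           absorbance within 1e-9", {
  set.seed(5)
  g <- small_grid(8)
  A <- array(runif(6 * 7 * 8, 0, 2), dim = c(6, 7, 8))
  cap <- simulate_capture(hypercube(A, g, "pseudo_absorbance"), noise_sd = 0)
  rec <- to_pseudo_absorbance(correct_reflectance(cap))
  expect_lt(max(abs(rec$values - A)), 1e-9)
})

test_that("calibration cancels any shared positive gain field", {
  set.seed(6)
  g <- small_grid(6)
  A <- array(runif(5 * 5 * 6, 0, 1.5), dim = c(5, 5, 6))
  cube <- hypercube(A, g, "pseudo_absorbance")
  base_gain <- default_gain_field(5, 5)
  r1 <- correct_reflectance(simulate_capture(cube, base_gain, noise_sd = 0))
  scale <- matrix(runif(25, 0.5, 3), 5, 5)
  r2 <- correct_reflectance(simulate_capture(cube, base_gain * scale,
                                             noise_sd = 0))
  expect_lt(max(abs(r1$values - r2$values)), 1e-9)
})

test_that("dataset streaming is balanced, treatment-cycling and reproducible
           from the seed", {
  plan <- capture_plan(3, seed = 9L)
  expect_identical(nrow(plan), 12L)
  expect_identical(as.vector(table(plan$category)), rep(3L, 4))
  expect_identical(plan$treatment[plan$category == "P1"],
                   paste0("fat_", c(0, 2.5, 5)))
  expect_identical(plan, capture_plan(3, seed = 9L))
  expect_true(all(plan$capture_seed < 2^31))

  sc <- small_scene()
  s1 <- generate_dataset(1, scene = sc, seed = 31L)
  s2 <- generate_dataset(1, scene = sc, seed = 31L)
  caps1 <- list(); repeat { x <- s1$next_capture(); if (is.null(x)) break
                           caps1[[length(caps1) + 1]] <- x }
  expect_length(caps1, 4L)
  expect_identical(vapply(caps1, `[[`, "", "label"), patty_categories())
  m1 <- extract_matrix(caps1)
  m2 <- extract_matrix(s2)
  expect_identical(m1$values, m2$values)  # bit-identical spectra
})
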