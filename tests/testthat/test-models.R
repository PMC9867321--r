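# Splitting, classifiers, LOOCV, grid search and the evaluation suite.

test_that("the stratified 70/30 split is exact, disjoint and reproducible", {
  sm <- toy_spectral_matrix(n_per_class = 200, n_channels = 6)
  parts <- split_matrix(sm, split_spec(0.70, seed = 7))
  expect_identical(nrow(parts$calibration$values), 560L)
  expect_identical(nrow(parts$validation$values), 240L)
  expect_identical(as.vector(table(parts$calibration$labels)), rep(140L, 4))
  expect_identical(sort(c(parts$calibration$sample_ids,
                          parts$validation$sample_ids)),
                   sort(sm$sample_ids))
  parts2 <- split_matrix(sm, split_spec(0.70, seed = 7))
  expect_identical(parts$cal_idx, parts2$cal_idx)
  expect_false(identical(parts$cal_idx,
                         split_matrix(sm, split_spec(0.70, seed = 8))$cal_idx))

  tiny <- toy_spectral_matrix(n_per_class = 1)
  expect_error(split_matrix(tiny, split_spec()), "< 2 samples")
  expect_error(split_spec(1.2), "train_fraction")
})

test_that("LOOCV is perfect on a separable toy, at chance on random labels,
           and refits once per sample", {
  # two far-apart classes on one channel
  set.seed(10)
  X <- matrix(rnorm(40 * 4, sd = 0.1), 40, 4)
  X[, 1] <- X[, 1] + rep(c(-10, 10), each = 20)
  sep <- spectral_matrix(X, small_grid(4),
                         labels = rep(c("P1", "P2"), each = 20))
  expect_equal(loocv(model_spec("lda", n_pcs = 2),
                     preprocessing_spec("mean_centre"), sep), 100)

  # random labels among 4 classes: accuracy ~ 25% within Monte Carlo 3 sigma
  set.seed(11)
  n <- 200
  rnd <- spectral_matrix(matrix(rnorm(n * 6), n, 6), small_grid(6),
                         labels = sample(patty_categories(), n,
                                         replace = TRUE))
  acc <- loocv(model_spec("knn", k_neighbours = 5),
               preprocessing_spec("mean_centre"), rnd)
  sigma <- 100 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(acc - 25), 3 * sigma)

  # refit-count contract: n = 3 samples -> exactly 3 refits
  calls <- 0L
  .S3method("predict", "stub_model",
            function(object, newdata, ...) object$lab)
  local_mocked_bindings(
    train_model = function(spec, prep, cal) {
      calls <<- calls + 1L
      structure(list(lab = as.character(cal$labels[1])), class = "stub_model")
    },
    .package = "pattyHSI"
  )
  three <- spectral_matrix(matrix(rnorm(9), 3, 3), small_grid(3),
                           labels = c("P1", "P1", "P2"))
  loocv(model_spec("lda"), preprocessing_spec("mean_centre"), three)
  expect_identical(calls, 3L)
})

test_that("grid search is exhaustive, returns singleton grids unchanged and
           finds the known-optimal cost on a margin-sensitive toy", {
  sm <- toy_spectral_matrix(n_per_class = 12, n_channels = 8, mu = 1.2,
                            noise = 0.6)
  base <- model_spec("svm", kernel = "linear", C = 1, gamma = 1)

  single <- grid_search(base, list(C = 42), preprocessing_spec("snv"), sm)
  expect_equal(single$best$C, 42)
  expect_identical(nrow(single$results), 1L)

  gs <- grid_search(base, list(C = c(1e-6, 1e-4, 10),
                               gamma = c(1, 2)),
                    preprocessing_spec("mean_centre"), sm, inner_folds = 3)
  expect_identical(nrow(gs$results), 6L)  # exhaustive: product of grid sizes

  # hyperparameter recovery: with unbalanced classes, a neighbourhood wider
  # than the minority classes collapses KNN onto the majority class, so the
  # known-good k must win (bad value first to exercise tie ordering)
  set.seed(41)
  Xk <- matrix(rnorm(48 * 6, sd = 0.3), 48, 6)
  labk <- rep(patty_categories(), c(30, 6, 6, 6))
  Xk[, 1] <- Xk[, 1] + 4 * as.integer(factor(labk))
  smk <- spectral_matrix(Xk, small_grid(6), labels = labk)
  gk <- grid_search(model_spec("knn"), list(k_neighbours = c(30, 5)),
                    preprocessing_spec("mean_centre"), smk, inner_folds = 3)
  expect_identical(gk$best$k_neighbours, 5L)
})

test_that("classifier constructions behave as documented on toys", {
  set.seed(12)
  # LDA on two well-separated clouds: perfect resubstitution
  X <- matrix(rnorm(30 * 5, sd = 0.2), 30, 5)
  X[, 2] <- X[, 2] + rep(c(0, 8), times = 15)
  sep <- spectral_matrix(X, small_grid(5),
                         labels = rep(c("P1", "P3"), times = 15))
  fit <- train_model(model_spec("lda", n_pcs = 2),
                     preprocessing_spec("mean_centre"), sep)
  expect_equal(multiclass_accuracy(sep$labels, predict(fit, sep)), 100)

  # KNN with k = 1 memorises any duplicate-free training set
  sm <- toy_spectral_matrix(n_per_class = 8, n_channels = 6, noise = 1)
  fit1 <- train_model(model_spec("knn", k_neighbours = 1),
                      preprocessing_spec("mean_centre"), sm)
  expect_equal(multiclass_accuracy(sm$labels, predict(fit1, sm)), 100)

  # decision trees with unconstrained depth memorise the calibration set
  fitd <- train_model(model_spec("dtree"), preprocessing_spec("mean_centre"),
                      sm)
  expect_equal(multiclass_accuracy(sm$labels, predict(fitd, sm)), 100)

  # n_pcs beyond the fittable rank errors
  expect_error(train_model(model_spec("lda", n_pcs = 10),
                           preprocessing_spec("mean_centre"),
                           toy_spectral_matrix(2, 6)), "n_pcs")
})

test_that("PLS-DA matches a hand-computed single-latent-variable fit and
           assigns classes by the largest dummy response", {
  # toy: classes differ on channel 1 only
  set.seed(13)
  n <- 24
  X <- cbind(rep(c(0, 4), each = n / 2), matrix(rnorm(n * 3, sd = 0.01),
                                                n, 3))
  labels <- rep(c("P1", "P2"), each = n / 2)
  sm <- spectral_matrix(X, small_grid(4), labels = labels)
  fit <- train_model(model_spec("plsda", n_latent_variables = 1),
                     preprocessing_spec("mean_centre"), sm)
  pred <- predict(fit, sm)
  expect_equal(as.character(pred), labels)

  # independent NIPALS oracle for one latent variable
  Xc <- scale(X, scale = FALSE)
  Y <- cbind(P1 = as.numeric(labels == "P1"), P2 = as.numeric(labels == "P2"))
  Yc <- scale(Y, scale = FALSE)
  w <- crossprod(Xc, Yc[, 1]); w <- w / sqrt(sum(w^2))
  t1 <- Xc %*% w
  q1 <- crossprod(Yc, t1) / sum(t1^2)
  p1 <- crossprod(Xc, t1) / sum(t1^2)
  B_oracle <- w %*% solve(crossprod(p1, w), t(q1))
  expect_equal(unname(fit$fit$B), unname(B_oracle), tolerance = 1e-6)
})

test_that("validation rows never influence calibration or CV results", {
  sm <- toy_spectral_matrix(n_per_class = 10, n_channels = 8)
  # non-stratified split: the partition depends only on (n, seed), so the
  # same indices are drawn for the original and the permuted matrix
  split <- split_spec(0.7, seed = 3, stratified = FALSE)
  parts <- split_matrix(sm, split)
  # permute labels and shuffle spectra among the validation rows only
  set.seed(33)
  perm <- sm
  val_rows <- setdiff(seq_len(nrow(sm$values)), parts$cal_idx)
  perm$labels[val_rows] <- sample(perm$labels[val_rows])
  perm$values[val_rows, ] <- perm$values[sample(val_rows), ]

  for (alg in list(model_spec("lda", n_pcs = 2),
                   model_spec("svm", kernel = "linear", C = 10, gamma = 1),
                   model_spec("plsda", n_latent_variables = 2))) {
    prep <- preprocessing_spec("snv")
    f1 <- train_model(alg, prep, split_matrix(sm, split)$calibration)
    f2 <- train_model(alg, prep, split_matrix(perm, split)$calibration)
    cal1 <- predict(f1, split_matrix(sm, split)$calibration)
    cal2 <- predict(f2, split_matrix(perm, split)$calibration)
    expect_identical(as.character(cal1), as.character(cal2))
    expect_equal(loocv(alg, prep, split_matrix(sm, split)$calibration),
                 loocv(alg, prep, split_matrix(perm, split)$calibration))
  }
})

test_that("label-permuted data drops every model to chance-level validation
           accuracy", {
  set.seed(14)
  n <- 160
  sm <- toy_spectral_matrix(n_per_class = n / 4, n_channels = 10, mu = 3)
  sm$labels <- factor(sample(as.character(sm$labels)),
                      levels = patty_categories())
  parts <- split_matrix(sm, split_spec(0.7, seed = 5))
  n_val <- nrow(parts$validation$values)
  sigma <- 100 * sqrt(0.25 * 0.75 / n_val)
  for (ms in default_model_suite("snv")) {
    fit <- train_model(ms, preprocessing_spec("snv"), parts$calibration)
    acc <- multiclass_accuracy(parts$validation$labels,
                               predict(fit, parts$validation))
    expect_lt(abs(acc - 25), 5 * sigma)
  }
})

test_that("classification degrades as compositional noise grows", {
  accs <- sapply(1:5, function(seed) {
    sapply(c(0.05, 0.5), function(js) {
      sc <- small_scene()
      sm <- extract_matrix(generate_dataset(6, scene = sc, jitter_sd = js,
                                            seed = 100 + seed))
      parts <- split_matrix(sm, split_spec(0.7, seed = seed))
      fit <- train_model(model_spec("svm", kernel = "linear", C = 10,
                                    gamma = 1),
                         preprocessing_spec("snv"), parts$calibration)
      multiclass_accuracy(parts$validation$labels,
                          predict(fit, parts$validation))
    })
  })
  expect_lt(mean(accs[2, ]), mean(accs[1, ]))
})

test_that("the evaluation suite covers every preprocessing x model cell with
           in-range accuracies", {
  sm <- toy_spectral_matrix(n_per_class = 6, n_channels = 10, mu = 4)
  recs <- evaluate_suite(sm, c("snv", "snv_detrend"),
                         split = split_spec(0.7, seed = 2), cv = TRUE)
  expect_identical(nrow(recs), 18L)
  expect_identical(as.vector(table(recs$preprocessing)), c(9L, 9L))
  expect_true(all(recs$cal >= 0 & recs$cal <= 100))
  expect_true(all(recs$cv >= 0 & recs$cv <= 100))
  expect_true(all(recs$val >= 0 & recs$val <= 100))
  expect_equal(recs$cal[recs$model == "D.Trees"], c(100, 100))
  expect_identical(recs$regulation, ifelse(recs$val >= 90, "acceptable",
                                           "rejected"))
})
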