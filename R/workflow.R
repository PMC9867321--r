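#' Pipeline configuration
#'
#' Builds and validates the configuration driving the end-to-end synthetic
#' study. Unknown keys are rejected so config typos fail before any compute.
#' Can be loaded from a YAML file with [read_pipeline_config()].
#'
#' @param generator List: `n_per_category`, `seed`, `jitter_sd`, `jitter_cor`,
#'   plus any [scene_spec()] arguments under `scene`.
#' @param segmentation List of [segmentation_params()] arguments.
#' @param preprocessing Character vector of preprocessing methods.
#' @param split List of [split_spec()] arguments.
#' @param cv Compute LOOCV columns in the evaluation (default TRUE).
#' @param output_dir Where `reproduce_study()`/`simulate_to_dir()` write.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), segmentation = list(),
                            preprocessing = c("snv", "snv_detrend"),
                            split = list(), cv = TRUE,
                            output_dir = tempfile("pattyhsi_run_")) {
  known_gen <- c("n_per_category", "seed", "jitter_sd", "jitter_cor", "scene")
  bad <- setdiff(names(generator), known_gen)
  if (length(bad))
    stop(sprintf("unknown generator keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.null(generator$scene)) {
    bad <- setdiff(names(generator$scene), names(formals(scene_spec)))
    if (length(bad))
      stop(sprintf("unknown scene keys: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  bad <- setdiff(names(segmentation), names(formals(segmentation_params)))
  if (length(bad))
    stop(sprintf("unknown segmentation keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  bad <- setdiff(names(split), names(formals(split_spec)))
  if (length(bad))
    stop(sprintf("unknown split keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg <- list(
    generator = utils::modifyList(
      list(n_per_category = 200L, seed = 42L, jitter_sd = 0.05,
           jitter_cor = 0.9, scene = list()), generator),
    segmentation = segmentation,
    preprocessing = preprocessing,
    split = split,
    cv = isTRUE(cv),
    output_dir = output_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys `generator`, `segmentation`,
#'   `preprocessing`, `split`, `cv`, `output_dir`.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("generator", "segmentation", "preprocessing", "split", "cv",
             "output_dir")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(pipeline_config, y)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(cfg)), f)
  unname(tools::md5sum(f))
}

write_manifest <- function(dir, cfg, stages, files) {
  manifest <- list(config_hash = config_hash(cfg),
                   seeds = list(generator = cfg$generator$seed,
                                split = cfg$split$seed %||%
                                  formals(split_spec)$seed),
                   stage_seconds = stages,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a synthetic study to disk
#'
#' Streams the planned captures to `output_dir`: one ENVI image (BIL,
#' float32) per capture with its wavelength list in the header, a JSON
#' sidecar carrying label, treatment, true composition and the child seed,
#' and the ground-truth mask as PNG. Memory use is bounded: one capture is
#' held at a time. A manifest (config hash, seeds, timings, file inventory)
#' is written last.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory.
#' @export
simulate_to_dir <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop(sprintf("output directory not writable: %s", dir), call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  g <- config$generator
  scene <- do.call(scene_spec, g$scene)
  stream <- generate_dataset(g$n_per_category, scene,
                             jitter_sd = g$jitter_sd,
                             jitter_cor = g$jitter_cor, seed = g$seed)
  files <- character()
  repeat {
    cap <- stream$next_capture()
    if (is.null(cap)) break
    base <- file.path(dir, cap$sample_id)
    cube <- hypercube(cap$R0, cap$grid, unit = "raw_irradiance")
    write_envi(cube, base, interleave = "bil")
    # references are shared across the session; store once
    refbase <- file.path(dir, "references")
    if (!file.exists(paste0(refbase, "_dark.hdr"))) {
      write_envi(hypercube(cap$D, cap$grid, "raw_irradiance"),
                 paste0(refbase, "_dark"))
      write_envi(hypercube(cap$W, cap$grid, "raw_irradiance"),
                 paste0(refbase, "_grey"))
    }
    sidecar <- list(sample_id = cap$sample_id, label = cap$label,
                    treatment = cap$treatment,
                    composition = as.list(unclass(cap$composition)))
    jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
    png::writePNG(cap$truth_mask * 1, paste0(base, "_mask.png"))
    files <- c(files, basename(paste0(base, c(".img", ".hdr", ".json",
                                              "_mask.png"))))
  }
  write_manifest(dir, config,
                 list(simulate = proc.time()[["elapsed"]] - t0),
                 files)
  message(sprintf("wrote %d captures to %s", stream$n, dir))
  invisible(dir)
}

#' Extract the spectral matrix from an on-disk dataset
#'
#' Reads every capture (ENVI image + JSON sidecar) in a directory written by
#' [simulate_to_dir()], runs calibration, segmentation and mean-spectrum
#' extraction, and writes/returns the labelled spectral matrix. Per-capture
#' failures are logged and excluded; the run completes with a nonzero
#' failure count instead of aborting.
#'
#' @param dataset_dir Directory from [simulate_to_dir()].
#' @param params [segmentation_params()].
#' @param csv Optional output CSV path (header row: sample_id, category,
#'   treatment, then wavelengths in nm).
#' @return A `spectral_matrix` (attribute `failures` lists skipped captures).
#' @export
extract_dir <- function(dataset_dir, params = segmentation_params(),
                        csv = NULL) {
  sidecars <- sort(list.files(dataset_dir, pattern = "\\.json$",
                              full.names = TRUE))
  sidecars <- sidecars[!basename(sidecars) %in% "manifest.json" &
                         !startsWith(basename(sidecars), "references")]
  if (!length(sidecars)) stop("empty dataset directory", call. = FALSE)
  dark <- read_envi(file.path(dataset_dir, "references_dark.hdr"))
  grey <- read_envi(file.path(dataset_dir, "references_grey.hdr"))
  caps <- list()
  failures <- character()
  for (sc in sidecars) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    cap <- tryCatch({
      cube <- read_envi(sub("\\.json$", ".hdr", sc))
      structure(list(R0 = cube$values, D = dark$values, W = grey$values,
                     grid = cube$grid, label = meta$label,
                     sample_id = meta$sample_id, treatment = meta$treatment),
                class = "raw_capture")
    }, error = function(e) e)
    if (inherits(cap, "error")) {
      failures <- c(failures, sprintf("%s: %s", meta$sample_id,
                                      conditionMessage(cap)))
      next
    }
    caps[[length(caps) + 1L]] <- cap
  }
  if (!length(caps)) stop("no readable captures in dataset", call. = FALSE)
  sm <- extract_matrix(caps, params)
  attr(sm, "failures") <- c(failures, attr(sm, "failures"))
  if (length(attr(sm, "failures")))
    message(sprintf("%d capture(s) failed and were excluded",
                    length(attr(sm, "failures"))))
  if (!is.null(csv)) write_spectral_csv(sm, csv)
  sm
}

#' Write a spectral matrix as CSV
#'
#' Columns: `sample_id`, `category`, `treatment`, then one column per
#' wavelength (nm).
#'
#' @param sm A `spectral_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectral_csv <- function(sm, path) {
  df <- data.frame(sample_id = sm$sample_ids,
                   category = as.character(sm$labels),
                   treatment = sm$treatments,
                   sm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral matrix written by [write_spectral_csv()]
#'
#' @param path CSV path.
#' @return A `spectral_matrix`.
#' @export
read_spectral_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("sample_id", "category", "treatment")
  wl <- as.numeric(setdiff(names(df), meta))
  step <- mean(diff(wl))
  grid <- wavelength_grid(wl[1], step, wl[length(wl)] + step / 2)
  spectral_matrix(as.matrix(df[, !(names(df) %in% meta)]), grid,
                  labels = df$category, sample_ids = df$sample_id,
                  treatments = df$treatment)
}

#' Reproduce the full synthetic study
#'
#' End-to-end driver: simulate the captures (in memory, streaming), extract
#' the spectral matrix, run PCA screening with one outlier
#' removal-and-refit pass, evaluate every preprocessing x model combination
#' on a single 70/30 stratified split, and write the report bundle
#' (evaluation table, per-class performance tables for the strong models,
#' PCA exports, manifest) to `config$output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return List: `evaluation` (the suite records), `performance` (per-class
#'   tables for LDA and the SVM kernels), `pca` (screening model),
#'   `outliers` (report), `matrix` (the cleaned `spectral_matrix`),
#'   `output_dir`.
#' @export
reproduce_study <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  tick <- function() proc.time()[["elapsed"]]

  t0 <- tick()
  g <- config$generator
  scene <- do.call(scene_spec, g$scene)
  stream <- generate_dataset(g$n_per_category, scene,
                             jitter_sd = g$jitter_sd,
                             jitter_cor = g$jitter_cor, seed = g$seed)
  params <- do.call(segmentation_params, config$segmentation)
  sm <- extract_matrix(stream, params)
  stages$extract <- tick() - t0

  t0 <- tick()
  screened <- screen_outliers(sm)
  sm <- screened$kept
  utils::write.csv(data.frame(component = seq_along(
    screened$pca$explained_variance_pct),
    explained_variance_pct = screened$pca$explained_variance_pct),
    file.path(dir, "pca_explained_variance.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = sm$sample_ids,
                              category = as.character(sm$labels),
                              screened$pca$scores),
                   file.path(dir, "pca_scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(flagged = screened$report$flagged,
         t2_limit = screened$report$t2_limit,
         q_limit = screened$report$q_limit,
         alpha = screened$report$alpha),
    file.path(dir, "outliers.json"), auto_unbox = TRUE, digits = NA)
  stages$pca <- tick() - t0

  t0 <- tick()
  split <- do.call(split_spec, config$split)
  evaluation <- evaluate_suite(sm, config$preprocessing, split = split,
                               cv = config$cv)
  utils::write.csv(evaluation, file.path(dir, "evaluation.csv"),
                   row.names = FALSE)
  stages$evaluate <- tick() - t0

  # per-class performance tables for the discriminant models of interest
  t0 <- tick()
  parts <- split_matrix(sm, split)
  strong <- list(lda = model_spec("lda", n_pcs = 2),
                 svm_rbf = model_spec("svm", kernel = "rbf", C = 1000,
                                      gamma = 0.001),
                 svm_linear = model_spec("svm", kernel = "linear", C = 10,
                                         gamma = 1),
                 svm_poly = model_spec("svm", kernel = "poly", C = 0.1,
                                       gamma = 0.1))
  performance <- list()
  for (pp in config$preprocessing) {
    prep <- preprocessing_spec(pp)
    for (nm in names(strong)) {
      fit <- train_model(strong[[nm]], prep, parts$calibration)
      tab <- performance_table(parts$validation$labels,
                               predict(fit, parts$validation))
      performance[[paste(nm, pp, sep = ".")]] <- tab
    }
  }
  perf_df <- do.call(rbind, Map(function(tab, nm) {
    cbind(model_preprocessing = nm, tab)
  }, performance, names(performance)))
  utils::write.csv(perf_df, file.path(dir, "performance_per_class.csv"),
                   row.names = FALSE)
  stages$performance <- tick() - t0

  write_manifest(dir, config, stages,
                 list.files(dir))
  list(evaluation = evaluation, performance = performance,
       pca = screened$pca, outliers = screened$report, matrix = sm,
       output_dir = dir)
}
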