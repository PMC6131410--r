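#' Run configuration for a full reproducible analysis
#'
#' A single configuration object drives [run_all()]: cohort generation,
#' feature extraction, split, model fit and reporting. It round-trips
#' through YAML unchanged via [write_run_config()] / [read_run_config()].
#'
#' @param n_lesions Cohort size (default 300, the demo scale).
#' @param effect_size Class texture effect size in `[0, 1]`
#'   (see [default_lesion_priors()]).
#' @param cohort_seed,split_seed,cv_seed Seeds for the three random stages.
#' @param Ng,wavelet,boundary,distance Extraction parameters
#'   (see [extraction_config()]).
#' @param split_fraction Training fraction.
#' @param n_folds CV folds.
#' @param subgroup_machine Machine id for the homogeneous subgroup refit.
#' @param birads_low Low-suspicion BI-RADS categories.
#' @param icc_n_lesions Lesions re-rated for the agreement analysis.
#' @param image_size Simulated image size.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_lesions = 300L, effect_size = 1,
                       cohort_seed = 1L, split_seed = 2L, cv_seed = 3L,
                       Ng = 64L, wavelet = "coif1", boundary = "periodic",
                       distance = 1L, split_fraction = 0.5, n_folds = 10L,
                       subgroup_machine = "iU22",
                       birads_low = c("3", "4a"), icc_n_lesions = 50L,
                       image_size = c(128L, 128L), out_dir = "radiomics_run") {
  cfg <- list(n_lesions = as.integer(n_lesions), effect_size = effect_size,
              cohort_seed = as.integer(cohort_seed),
              split_seed = as.integer(split_seed),
              cv_seed = as.integer(cv_seed),
              Ng = as.integer(Ng), wavelet = wavelet, boundary = boundary,
              distance = as.integer(distance),
              split_fraction = split_fraction,
              n_folds = as.integer(n_folds),
              subgroup_machine = subgroup_machine,
              birads_low = birads_low,
              icc_n_lesions = as.integer(icc_n_lesions),
              image_size = as.integer(image_size), out_dir = out_dir)
  extraction_config(cfg$Ng, cfg$wavelet, cfg$boundary, cfg$distance)
  stopifnot(cfg$n_lesions >= 20L, cfg$split_fraction > 0,
            cfg$split_fraction < 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Serialize a fitted model (with calibration) to JSON
#'
#' @param model A `radiomics_model`.
#' @param calibration A [score_calibration()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, calibration, path) {
  stopifnot(inherits(model, "radiomics_model"))
  obj <- list(
    selected_features = model$selected_features,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    lambda = model$lambda,
    standardization = list(
      mean = as.list(model$standardization$mean[model$selected_features]),
      sd = as.list(model$standardization$sd[model$selected_features])),
    calibration = list(intercept = calibration$intercept,
                       slope = calibration$slope))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the complete pipeline: generate, extract, fit, report
#'
#' Generates a synthetic cohort, extracts the 730-feature table, fits the
#' radiomics score with its calibration, writes the split-balance,
#' performance-by-machine and subgroup tables, runs the two-rater ICC
#' agreement analysis on a re-rated lesion subset, and emits a manifest
#' with the configuration and MD5 hashes of every artifact. Re-running
#' with the same configuration reproduces all CSV artifacts byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort, feature table, report,
#'   agreement table and manifest.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out, "images")
  tab_dir <- file.path(out, "tables")
  dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)

  spec <- cohort_spec(config$n_lesions, seed = config$cohort_seed)
  cohort <- generate_cohort(spec, img_dir,
                            priors = default_lesion_priors(config$effect_size),
                            image_size = config$image_size)
  write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)

  ec <- extraction_config(config$Ng, config$wavelet, config$boundary,
                          config$distance)
  features <- extract_cohort(cohort, ec,
                             out_csv = file.path(out, "features.csv"))
  features <- split_train_validation(features, config$split_fraction,
                                     config$split_seed)
  report <- run_analysis(features, cv_seed = config$cv_seed,
                         n_folds = config$n_folds,
                         subgroup_machine = config$subgroup_machine,
                         birads_low = config$birads_low,
                         out_dir = tab_dir)
  write_model_json(report$model, report$calibration,
                   file.path(out, "model.json"))

  # interobserver agreement on a re-rated subset: rater 2 = perturbed ROI
  n_icc <- min(config$icc_n_lesions, nrow(cohort))
  idx <- with_seed(config$cohort_seed + 1L,
                   sample.int(nrow(cohort), n_icc))
  sub <- cohort[idx, , drop = FALSE]
  r2 <- vector("list", n_icc)
  for (k in seq_len(n_icc)) {
    img <- load_image(sub$image_path[k])
    msk <- perturb_mask(load_mask(sub$mask_path[k]),
                        seed = config$cohort_seed + k)
    r2[[k]] <- extract_all(img, msk, ec)
  }
  f1 <- features[match(sub$lesion_id, features$lesion_id), , drop = FALSE]
  f2 <- cbind(sub[, "lesion_id", drop = FALSE],
              as.data.frame(do.call(rbind, r2)))
  icc_tab <- icc_summary_table(f1, f2)
  write.csv(icc_tab, file.path(tab_dir, "interobserver_icc.csv"),
            row.names = FALSE)

  write_run_config(config, file.path(out, "run_config.yaml"))
  artifacts <- c(file.path(out, c("cohort.csv", "features.csv",
                                  "model.json", "run_config.yaml")),
                 list.files(tab_dir, full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("usradiomics")),
    config = unclass(config),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(artifacts)),
      basename(artifacts))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, features = features, report = report,
                 agreement = icc_tab, manifest = manifest))
}
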