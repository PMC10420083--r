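#' Run the full yield-estimation pipeline
#'
#' Chains every stage end to end: (optionally) simulate a synthetic
#' nitrogen-gradient scene, encode it to raw DN with calibration panels,
#' fit and apply the empirical-line calibration, unmix the reflectance into
#' flower/leaf/soil abundances, compute vegetation indices, aggregate to
#' plot level, fit and cross-validate the 27 yield models, and (optionally)
#' assess a classification confusion matrix. All intermediate rasters,
#' tables and a manifest (inputs, seed, option flags, per-file MD5
#' checksums) are written under `out_dir`; given the same config and seed
#' the outputs are byte-identical.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   entries: `seed` (integer, default 1), `out_dir` (required),
#'   `sensor` (`"UAV6"`, `"QUAD4"`, or a sensor JSON path),
#'   `endmember_library` (CSV path; `NULL` = synthesise from the seed),
#'   `snr_db`, `jitter_conc`, `bit_depth`, `vi_convention`, `rdvi_variant`,
#'   `cv_variant`, `confusion_matrix` (CSV/JSON path, optional), plus any
#'   [trial_design()] fields under `design`.
#' @return Invisibly, a list with the predictor `table`, the model
#'   `ranking`, the fitted `gain_bias`, the `truth` bundle, optional
#'   confusion `metrics`, and the `manifest` path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(seed = 1L, sensor = "UAV6", endmember_library = NULL, snr_db = 40,
         jitter_conc = 300, bit_depth = 8L, vi_convention = "mean_reflectance",
         rdvi_variant = "sqrt", cv_variant = "rmse_over_mean",
         confusion_matrix = NULL, design = list()),
    config
  )
  if (is.null(cfg$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  for (p in c(cfg$endmember_library, cfg$confusion_matrix)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input not found: ", p, call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sensor <- resolve_sensor(cfg$sensor)
  library <- if (is.null(cfg$endmember_library)) {
    generate_endmember_library(cfg$seed)
  } else {
    read_endmember_library(cfg$endmember_library)
  }

  design <- do.call(trial_design, utils::modifyList(list(seed = cfg$seed),
                                                    as.list(cfg$design)))
  trial <- generate_trial(design, library = library, sensor = sensor)
  scene <- render_scene(trial, snr_db = cfg$snr_db,
                        jitter_conc = cfg$jitter_conc)
  dn <- encode_dn(scene$reflectance, bit_depth = cfg$bit_depth)

  gb <- fit_elm(extract_panels(dn))
  refl <- drop_panel_strip(apply_elm(dn, gb))
  E <- build_endmember_matrix(library, sensor)
  abund <- unmix_image(refl, E)
  table <- plot_aggregate(refl, abund, trial$plots,
                          vi_convention = cfg$vi_convention,
                          rdvi_variant = cfg$rdvi_variant)
  ranking <- rank_models(table, cv_variant = cfg$cv_variant)
  metrics <- NULL
  if (!is.null(cfg$confusion_matrix)) {
    metrics <- confusion_metrics(read_confusion(cfg$confusion_matrix))
  }

  paths <- list(
    reflectance = file.path(cfg$out_dir, "reflectance.tif"),
    dn = file.path(cfg$out_dir, "dn.tif"),
    abundance = file.path(cfg$out_dir, "abundance.tif"),
    truth = file.path(cfg$out_dir, "abundance_truth.tif"),
    plots = file.path(cfg$out_dir, "plots.csv"),
    table = file.path(cfg$out_dir, "predictors.csv"),
    ranking = file.path(cfg$out_dir, "model_ranking.csv"),
    gain_bias = file.path(cfg$out_dir, "calibration.json")
  )
  write_raster(refl, paths$reflectance)
  write_raster(dn, paths$dn)
  write_raster(abund, paths$abundance)
  write_raster(scene$truth, paths$truth)
  utils::write.csv(format(trial$plots, digits = 10), paths$plots, row.names = FALSE)
  utils::write.csv(format(table, digits = 10), paths$table, row.names = FALSE)
  utils::write.csv(format(ranking, digits = 10), paths$ranking, row.names = FALSE)
  jsonlite::write_json(gb, paths$gain_bias, auto_unbox = TRUE, digits = NA)
  if (!is.null(metrics)) {
    jsonlite::write_json(
      list(glance = glance(metrics), by_class = tidy(metrics)),
      file.path(cfg$out_dir, "accuracy.json"),
      auto_unbox = TRUE, digits = NA
    )
    paths$accuracy <- file.path(cfg$out_dir, "accuracy.json")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("canopymix")),
    seed = cfg$seed,
    options = cfg[c("sensor", "snr_db", "jitter_conc", "bit_depth",
                    "vi_convention", "rdvi_variant", "cv_variant")],
    beta_truth = as.list(trial$beta),
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(table = table, ranking = ranking, gain_bias = gb,
                 truth = trial, abundance = abund, metrics = metrics,
                 manifest = manifest_path))
}

resolve_sensor <- function(sensor) {
  if (inherits(sensor, "sensor_model")) return(sensor)
  if (identical(sensor, "UAV6")) return(sensor_uav6())
  if (identical(sensor, "QUAD4")) return(sensor_quad4())
  if (is.character(sensor) && file.exists(sensor)) return(read_sensor_json(sensor))
  stop("unknown sensor: ", sensor, call. = FALSE)
}
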