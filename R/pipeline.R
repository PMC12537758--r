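# Decision layer and end-to-end orchestration.
#
# The deployed diagnostic averages two probability streams: the
# growth-stage tabular classifier (5-class output collapsed to the
# 3-level scheme) and the image fusion network (3-class). The averaged
# vector maps to one of three irrigation recommendations.

#' Fuse tabular and image probabilities
#'
#' Element-wise arithmetic mean of two 3-class probability vectors (on
#' the canonical [stress_levels3()] order), renormalized. The label is
#' the argmax; exact ties break to the first label in canonical order
#' and set the `ambiguous` flag.
#'
#' @param p_tabular 3-class probability vector from the stage model
#'   (collapse a 5-class vector with [collapse_proba_5to3()] first).
#' @param p_image 3-class probability vector from the fusion model.
#' @return A `fused_decision`: list with `p_tabular`, `p_image`,
#'   `p_final`, `label`, `display`, `recommendation`, `ambiguous`.
#' @export
fuse_decision <- function(p_tabular, p_image) {
  if (length(p_tabular) != length(p_image)) {
    stop_invalid("probability vectors differ in length (",
                 length(p_tabular), " vs ", length(p_image), ")")
  }
  if (length(p_tabular) != 3L) {
    stop_invalid("decision fusion expects 3-class probability vectors")
  }
  for (v in list(p_tabular, p_image)) {
    check_range(v, 0, 1, "probabilities")
    if (abs(sum(v) - 1) > 1e-6) {
      stop_invalid("probabilities must sum to 1 (got ", sum(v), ")")
    }
  }
  p <- (as.numeric(p_tabular) + as.numeric(p_image)) / 2
  p <- p / sum(p)
  names(p) <- stress_levels3()
  top <- max(p)
  winners <- which(p >= top - 1e-12)
  label <- stress_levels3()[winners[1]]
  structure(list(
    p_tabular = stats::setNames(as.numeric(p_tabular), stress_levels3()),
    p_image = stats::setNames(as.numeric(p_image), stress_levels3()),
    p_final = p, label = label,
    display = unname(stress3_display()[label]),
    recommendation = recommend(label),
    ambiguous = length(winners) > 1L
  ), class = "fused_decision")
}

#' Irrigation recommendation for a stress level
#'
#' Dry-side stress initiates irrigation, optimal conditions are
#' maintained, wet-side stress reduces watering.
#'
#' @param label A 3-level stress code (see [stress_levels3()]).
#' @return One of `"initiate_irrigation"`, `"maintain"`,
#'   `"reduce_watering"`.
#' @export
recommend <- function(label) {
  map <- c(DRY_SIDE = "initiate_irrigation", OPTIMAL = "maintain",
           WET_SIDE = "reduce_watering")
  label <- as.character(label)
  if (!all(label %in% names(map))) {
    stop_invalid("unknown 3-level label: ",
                 paste(setdiff(label, names(map)), collapse = ", "))
  }
  unname(map[label])
}

#' Run configuration
#'
#' Schema-validated configuration for [run_pipeline()], loadable from
#' YAML. Sections: `out_dir`, `seed`, `generator` (arguments of
#' [generator_config()]), `cwsi` ([cwsi_parameters()] arguments),
#' `fusion` ([fusion_config()] arguments), `stage`, `tabular_kind`.
#'
#' @param out_dir Artifact directory.
#' @param seed Master seed; module seeds derive from it.
#' @param generator,cwsi,fusion Argument lists for the module configs.
#' @param stage Growth stage the tabular model serves.
#' @param tabular_kind Tabular model family (default `"KNN"`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = "cwsifusion_run", seed = 42L,
                       generator = list(), cwsi = list(),
                       fusion = list(), stage = "early",
                       tabular_kind = "KNN") {
  if (!stage %in% unname(stage_months())) {
    stop_invalid("stage must be one of ",
                 paste(unname(stage_months()), collapse = ", "),
                 class = "cwsifusion_config_error")
  }
  if (!tabular_kind %in% model_kinds()) {
    stop_invalid("tabular_kind must be one of ",
                 paste(model_kinds(), collapse = ", "),
                 class = "cwsifusion_config_error")
  }
  generator$seed <- generator$seed %||% seed
  fusion$seed <- fusion$seed %||% seed
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 generator = do.call(generator_config, generator),
                 cwsi = do.call(cwsi_parameters, cwsi),
                 fusion = do.call(fusion_config, fusion),
                 stage = stage, tabular_kind = tabular_kind),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are `run_config` arguments.
#' @export
run_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_invalid("unknown run_config key(s): ",
                 paste(unknown, collapse = ", "),
                 class = "cwsifusion_config_error")
  }
  do.call(run_config, cfg)
}

pipeline_log <- function(config, command, extra = list()) {
  dir.create(file.path(config$out_dir, "logs"), recursive = TRUE,
             showWarnings = FALSE)
  entry <- c(list(
    command = command, seed = config$seed,
    stage = config$stage, tabular_kind = config$tabular_kind,
    package_version = as.character(utils::packageVersion("cwsifusion")),
    config_hash = config_hash(config)
  ), extra)
  path <- file.path(config$out_dir, "logs", paste0(command, ".json"))
  jsonlite::write_json(entry, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  # stable content hash of the configuration (serialization-based)
  raw <- serialize(lapply(unclass(config), unclass), NULL, version = 2)
  sum(as.integer(raw) * (seq_along(raw) %% 997)) %% 1e9
}

#' Run a pipeline stage
#'
#' Command-line style orchestration over the package modules. Every
#' command writes its artifacts under `config$out_dir` plus a JSON log
#' recording seeds, a configuration hash and the package version.
#'
#' Commands: `simulate` (generate and write the synthetic dataset),
#' `cwsi` (append index columns to the manifest), `calibrate-rgb` (fit a
#' checker correction and apply it to all images), `extract-temp`
#' (three-region leaf temperatures), `train-tabular`, `train-fusion`,
#' `evaluate` (cross-validated tabular comparison), `explain` (Grad-CAM
#' maps for a sample), `predict` (fused decision and recommendation for
#' a sample).
#'
#' @param config A [run_config()].
#' @param command Command name.
#' @param sample_id Sample to explain/predict (default: first).
#' @param observed_checker_csv For `calibrate-rgb`: CSV of 24 observed
#'   patch RGB rows.
#' @return Invisible list of artifact paths / results, command-specific.
#' @export
run_pipeline <- function(config, command, sample_id = NULL,
                         observed_checker_csv = NULL) {
  stopifnot(inherits(config, "run_config"))
  commands <- c("simulate", "cwsi", "calibrate-rgb", "extract-temp",
                "train-tabular", "train-fusion", "evaluate", "explain",
                "predict")
  if (!command %in% commands) {
    stop_invalid("unknown command: ", command, " (expected one of ",
                 paste(commands, collapse = ", "), ")",
                 class = "cwsifusion_usage_error")
  }
  out <- config$out_dir
  data_dir <- file.path(out, "data")
  switch(command,
    "simulate" = {
      ds <- generate_dataset(config$generator)
      write_dataset(ds, data_dir)
      pipeline_log(config, command, list(n_samples = length(ds$samples)))
      invisible(list(data_dir = data_dir, n = length(ds$samples)))
    },
    "cwsi" = {
      manifest <- utils::read.csv(file.path(data_dir, "tables",
                                            "manifest.csv"))
      tab <- compute_cwsi_table(manifest[, c("sample_id", "leaf_temp_c",
                                             "air_temp_c",
                                             "rel_humidity_pct",
                                             "vwc_pct")], config$cwsi)
      path <- file.path(data_dir, "tables", "cwsi.csv")
      write_cwsi_table(tab, path)
      pipeline_log(config, command, list(rows = nrow(tab)))
      invisible(list(path = path, table = tab))
    },
    "calibrate-rgb" = {
      if (is.null(observed_checker_csv)) {
        stop_invalid("calibrate-rgb needs observed_checker_csv",
                     class = "cwsifusion_usage_error")
      }
      obs <- color_checker_observation(
        as.matrix(utils::read.csv(observed_checker_csv, header = FALSE)))
      cm <- fit_color_correction(obs)
      manifest <- utils::read.csv(file.path(data_dir, "tables",
                                            "manifest.csv"))
      cal_dir <- file.path(data_dir, "calibrated")
      dir.create(cal_dir, recursive = TRUE, showWarnings = FALSE)
      for (p in manifest$rgb_path) {
        img <- apply_color_correction(read_rgb_image(file.path(data_dir, p)),
                                      cm)
        write_rgb_image(img, file.path(cal_dir, basename(p)))
      }
      jsonlite::write_json(list(matrix = cm$matrix,
                                residual_ss = cm$residual_ss),
                           file.path(out, "correction_matrix.json"),
                           digits = NA)
      pipeline_log(config, command,
                   list(residual_ss = cm$residual_ss))
      invisible(list(correction = cm, dir = cal_dir))
    },
    "extract-temp" = {
      manifest <- utils::read.csv(file.path(data_dir, "tables",
                                            "manifest.csv"))
      rows <- lapply(seq_len(nrow(manifest)), function(i) {
        fr <- read_thermal_frame(file.path(data_dir,
                                           manifest$thermal_path[i]))
        rs <- read_region_masks(file.path(data_dir, "regions",
                                          paste0(manifest$sample_id[i],
                                                 ".json")))
        lt <- extract_leaf_temperature(fr, rs)
        data.frame(sample_id = manifest$sample_id[i],
                   region1 = lt$region_means[1],
                   region2 = lt$region_means[2],
                   region3 = lt$region_means[3],
                   leaf_temp_c = lt$leaf_temp_c)
      })
      tab <- do.call(rbind, rows)
      path <- file.path(data_dir, "tables", "leaf_temps.csv")
      utils::write.csv(tab, path, row.names = FALSE)
      pipeline_log(config, command, list(rows = nrow(tab)))
      invisible(list(path = path, table = tab))
    },
    "train-tabular" = {
      ind <- utils::read.csv(file.path(data_dir, "tables",
                                       "indicators.csv"))
      ind <- ind[ind$stage == config$stage, ]
      ranking <- rank_features(ind, seed = config$seed,
                               stage = config$stage)
      feats <- select_top_k(ranking, 4L)
      model <- fit_stage_model(config$tabular_kind, ind, feats,
                               seed = config$seed, stage = config$stage)
      mdir <- file.path(out, "models")
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(mdir, paste0("tabular_", config$stage, ".rds"))
      save_stage_model(model, path)
      pipeline_log(config, command,
                   list(features = feats, n = nrow(ind)))
      invisible(list(model_path = path, features = feats))
    },
    "train-fusion" = {
      manifest <- utils::read.csv(file.path(data_dir, "tables",
                                            "manifest.csv"))
      arrays <- load_pair_arrays(data_dir, manifest,
                                 config$fusion$input_side)
      model <- build_fusion_model(config$fusion)
      model <- train_fusion(model, arrays$rgb, arrays$thermal,
                            arrays$labels)
      mdir <- file.path(out, "models")
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(mdir, "fusion.rds")
      save_fusion_model(model, path)
      pipeline_log(config, command,
                   list(epochs = nrow(model$history),
                        best_epoch = model$best_epoch))
      invisible(list(model_path = path, history = model$history))
    },
    "evaluate" = {
      ind <- utils::read.csv(file.path(data_dir, "tables",
                                       "indicators.csv"))
      ind <- ind[ind$stage == config$stage, ]
      plan <- make_stratified_folds(ind$label, k = 5L, seed = config$seed)
      reports <- evaluate_stage_models(ind, plan, seed = config$seed)
      rdir <- file.path(out, "reports")
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      summary <- data.frame(
        kind = names(reports),
        mean_accuracy = vapply(reports, `[[`, numeric(1),
                               "mean_accuracy"),
        sd_accuracy = vapply(reports, `[[`, numeric(1), "sd_accuracy"))
      utils::write.csv(summary, file.path(rdir, "tabular_cv.csv"),
                       row.names = FALSE)
      for (k in names(reports)) {
        write_confusion_csv(reports[[k]]$confusion,
                            file.path(rdir, paste0("confusion_", k,
                                                   ".csv")))
      }
      pipeline_log(config, command,
                   list(best = summary$kind[which.max(
                     summary$mean_accuracy)]))
      invisible(list(summary = summary, reports = reports))
    },
    "explain" = {
      model <- load_fusion_model(file.path(out, "models", "fusion.rds"))
      s <- load_sample(data_dir, sample_id)
      rgb <- preprocess_for_model(s$rgb, model$config$input_side)
      th <- preprocess_for_model(s$thermal, model$config$input_side)
      edir <- file.path(out, "explanations")
      dir.create(edir, recursive = TRUE, showWarnings = FALSE)
      paths <- list()
      for (br in c("rgb", "thermal")) {
        hm <- grad_cam(model, rgb, th, branch = br)
        base <- file.path(edir, paste0(s$id, "_", br))
        write_heatmap(hm, paste0(base, ".csv"),
                      overlay_png = paste0(base, ".png"),
                      image = s$rgb)
        paths[[br]] <- paste0(base, ".csv")
      }
      pipeline_log(config, command, list(sample = s$id))
      invisible(paths)
    },
    "predict" = {
      fusion <- load_fusion_model(file.path(out, "models", "fusion.rds"))
      tab_model <- load_stage_model(file.path(out, "models",
                                              paste0("tabular_",
                                                     config$stage,
                                                     ".rds")))
      s <- load_sample(data_dir, sample_id)
      rgb <- preprocess_for_model(s$rgb, fusion$config$input_side)
      th <- preprocess_for_model(s$thermal, fusion$config$input_side)
      p_img <- predict_proba(fusion, rgb, th)[1, ]
      ind <- utils::read.csv(file.path(data_dir, "tables",
                                       "indicators.csv"))
      row <- ind[ind$sample_id == s$id, ]
      p5 <- predict(tab_model, row)$proba[1, ]
      p_tab <- collapse_proba_5to3(p5)
      decision <- fuse_decision(p_tab, p_img)
      path <- file.path(out, paste0("prediction_", s$id, ".json"))
      jsonlite::write_json(list(
        sample = s$id, p_tabular = decision$p_tabular,
        p_image = decision$p_image, p_final = decision$p_final,
        label = decision$label, display = decision$display,
        recommendation = decision$recommendation,
        ambiguous = decision$ambiguous
      ), path, auto_unbox = TRUE, digits = NA)
      pipeline_log(config, command,
                   list(sample = s$id, label = decision$label,
                        recommendation = decision$recommendation))
      invisible(decision)
    }
  )
}

load_sample <- function(data_dir, sample_id = NULL) {
  manifest <- utils::read.csv(file.path(data_dir, "tables",
                                        "manifest.csv"))
  i <- if (is.null(sample_id)) 1L else match(sample_id,
                                             manifest$sample_id)
  if (is.na(i)) stop_invalid("unknown sample id: ", sample_id)
  list(id = manifest$sample_id[i],
       rgb = read_rgb_image(file.path(data_dir, manifest$rgb_path[i])),
       thermal = read_thermal_frame(file.path(data_dir,
                                              manifest$thermal_path[i])))
}

load_pair_arrays <- function(data_dir, manifest, side) {
  n <- nrow(manifest)
  rgb <- array(0, c(n, side, side, 3))
  th <- array(0, c(n, side, side, 1))
  for (i in seq_len(n)) {
    rgb[i, , , ] <- preprocess_for_model(
      read_rgb_image(file.path(data_dir, manifest$rgb_path[i])), side)
    th[i, , , ] <- preprocess_for_model(
      read_thermal_frame(file.path(data_dir, manifest$thermal_path[i])),
      side)
  }
  list(rgb = rgb, thermal = th, labels = manifest$label3)
}
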