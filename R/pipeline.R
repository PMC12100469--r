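# Experiment orchestration: simulate -> preprocess -> train -> convert ->
# evaluate as one reproducible run, with the three-arm ablation
# (baseline / rotation / rotation_zoom) and a comparison table.

#' Experiment configuration
#'
#' One master seed fans out deterministically to dataset generation, fold
#' split, weight initialization and batch shuffling.  Arms: `"baseline"`
#' (no canonical rotation, no augmentation), `"rotation"` (canonical
#' beam-frame rotation), `"rotation_zoom"` (rotation plus zoom factors
#' 0.8 and 1.2).
#'
#' @param arm one of `"baseline"`, `"rotation"`, `"rotation_zoom"`.
#' @param master_seed integer.
#' @param n_train_beams,n_test_beams dataset size.
#' @param grid_shape,spacing_mm simulation and tensor lattice (the tensor
#'   reuses the simulation grid).
#' @param beams_per_plan beams per synthetic patient.
#' @param dataset_opts overrides for the simulator (see [make_dataset]).
#' @param model,train a [model_config] / [train_config]; train's seed and
#'   n_folds are taken from here.
#' @param zoom_factors augmentation factors for the `rotation_zoom` arm.
#' @param hu_window CT normalization window.
#' @param out_dir output directory or `NULL` (in-memory only).
#' @return a validated config list (class `experiment_config`).
#' @export
experiment_config <- function(arm = c("rotation", "baseline", "rotation_zoom"),
                              master_seed = 1,
                              n_train_beams = 18, n_test_beams = 6,
                              grid_shape = c(16, 24, 24), spacing_mm = 5,
                              beams_per_plan = 3,
                              dataset_opts = list(
                                sigma_peak = 5, sigma_d = 3,
                                sigma_growth = 0.10,
                                cavity_semi_range = c(7, 12),
                                slab_thickness_range = c(8, 14),
                                slab_width_range = c(20, 45),
                                n_air_cavities = 3, n_bone_slabs = 3,
                                pb_beamlet_width_mm = 30),
                              model = model_config(n_levels = 3,
                                                   base_features = 4,
                                                   growth_features = 4),
                              train = train_config(max_epochs = 60,
                                                   batch_size = 1,
                                                   seed = master_seed),
                              zoom_factors = c(0.8, 1.2),
                              hu_window = c(-1000, 2000),
                              out_dir = NULL) {
  arm <- match.arg(arm)
  cfg <- list(arm = arm, master_seed = as.integer(master_seed),
              n_train_beams = n_train_beams, n_test_beams = n_test_beams,
              grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              beams_per_plan = beams_per_plan, dataset_opts = dataset_opts,
              model = model, train = train, zoom_factors = zoom_factors,
              hu_window = hu_window, out_dir = out_dir)
  if (any(cfg$grid_shape %% 2^(model$n_levels - 1) != 0))
    stop("grid_shape must be divisible by 2^(n_levels-1)")
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from JSON
#'
#' Named fields in the file override the [experiment_config] defaults;
#' unknown fields are an error.
#'
#' @param path JSON file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  for (nm in c("model", "train"))
    if (!is.null(raw[[nm]]))
      raw[[nm]] <- do.call(if (nm == "model") model_config else train_config,
                           raw[[nm]])
  do.call(experiment_config, raw)
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL   # provenance is content-based, not path-based
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

canonicalize_dataset <- function(ds, cfg) {
  canon_cfg <- canonical_config(shape = cfg$grid_shape,
                                spacing_mm = cfg$spacing_mm,
                                hu_window = cfg$hu_window,
                                rotate = cfg$arm != "baseline")
  lapply(ds$beams, function(b)
    c(to_canonical(b$ct, b$pb, b$mc, b$beam, canon_cfg,
                   body = b$body, ctv = b$ctv),
      list(id = b$id, plan = b$plan, split = b$split)))
}

#' Run one experiment arm end-to-end
#'
#' Generates the synthetic dataset, canonicalizes it per the arm,
#' trains the fold ensemble, converts the held-out test beams, and
#' evaluates DL-vs-MC and PB-vs-MC per beam (gamma 3%/3 mm, ARD R90/R50,
#' MAE) and per plan (gamma 1/2/3%-mm, MAE, isodose DSC, DVH RDE).
#' Fully deterministic given `config$master_seed`.
#'
#' @param config an [experiment_config].
#' @param dataset optionally a pre-built `beam_dataset` (so several arms
#'   can share one dataset); must match the config geometry.
#' @param verbose print stage progress.
#' @return a report bundle (class `experiment_report`): per-beam table,
#'   plan reports, summary statistics, the trained `ensemble`, training
#'   histories, and provenance (config hash, seed).
#' @export
run_experiment <- function(config, dataset = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  stage <- function(msg) if (verbose) message(sprintf("[%s] %s",
                                                      format(Sys.time(), "%H:%M:%S"), msg))
  stage(paste("arm:", config$arm))
  if (is.null(dataset)) {
    stage("simulating dataset")
    dataset <- make_dataset(config$n_train_beams, config$n_test_beams,
                            master_seed = config$master_seed,
                            shape = config$grid_shape,
                            spacing_mm = config$spacing_mm,
                            beams_per_plan = config$beams_per_plan,
                            opts = config$dataset_opts)
  }
  stage("canonicalizing")
  samples <- canonicalize_dataset(dataset, config)
  is_train <- vapply(samples, function(s) s$split == "train", TRUE)
  train_samples <- samples[is_train]
  test_samples <- samples[!is_train]
  plan_ids <- vapply(train_samples, function(s) s$plan, "")

  stage("training folds")
  ensemble <- train_ensemble(
    train_samples, plan_ids, config$train, config$model,
    zoom_factors = if (config$arm == "rotation_zoom") config$zoom_factors,
    verbose = verbose)

  stage("converting and evaluating test beams")
  test_recs <- dataset$beams[!is_train]
  per_beam <- data.frame()
  dl_doses <- list()
  for (i in seq_along(test_samples)) {
    s <- test_samples[[i]]; b <- test_recs[[i]]
    dl_norm <- predict_ensemble(ensemble, s)
    dl <- from_canonical(dl_norm, s, b$mc)
    dl_doses[[b$id]] <- dl
    rep_b <- evaluate_beam(b$mc, dl, b$pb, b$beam, b$body)
    per_beam <- rbind(per_beam, data.frame(
      id = b$id, plan = b$plan,
      gamma_dl = rep_b$dl$gamma_pass, gamma_pb = rep_b$pb$gamma_pass,
      ard_r90_dl = rep_b$dl$ard_r90, ard_r90_pb = rep_b$pb$ard_r90,
      ard_r50_dl = rep_b$dl$ard_r50, ard_r50_pb = rep_b$pb$ard_r50,
      mae_dl = rep_b$dl$mae, mae_pb = rep_b$pb$mae))
  }

  stage("plan-level evaluation")
  plans <- unique(per_beam$plan)
  plan_reports <- lapply(plans, function(p) {
    sel <- which(vapply(test_recs, function(b) b$plan == p, TRUE))
    mc_list <- lapply(test_recs[sel], `[[`, "mc")
    pb_list <- lapply(test_recs[sel], `[[`, "pb")
    dl_list <- dl_doses[vapply(test_recs[sel], `[[`, "", "id")]
    presc <- sum(vapply(test_recs[sel], function(b) b$beam$prescribed_dose, 0))
    list(plan = p,
         dl = evaluate_plan(mc_list, dl_list, test_recs[[sel[1]]]$body,
                            test_recs[[sel[1]]]$ctv, presc),
         pb = evaluate_plan(mc_list, pb_list, test_recs[[sel[1]]]$body,
                            test_recs[[sel[1]]]$ctv, presc))
  })

  summary <- list(
    arm = config$arm,
    n_test_beams = nrow(per_beam),
    mean_gamma_dl = mean(per_beam$gamma_dl),
    mean_gamma_pb = mean(per_beam$gamma_pb),
    mean_mae_dl = mean(per_beam$mae_dl),
    mean_mae_pb = mean(per_beam$mae_pb),
    mean_ard_r90_dl = mean(per_beam$ard_r90_dl, na.rm = TRUE),
    mean_ard_r90_pb = mean(per_beam$ard_r90_pb, na.rm = TRUE),
    mean_ard_r50_dl = mean(per_beam$ard_r50_dl, na.rm = TRUE),
    mean_ard_r50_pb = mean(per_beam$ard_r50_pb, na.rm = TRUE))

  report <- structure(list(
    config = config, config_hash = config_hash(config),
    master_seed = config$master_seed,
    per_beam = per_beam, plan_reports = plan_reports, summary = summary,
    histories = ensemble$histories, ensemble = ensemble,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "experiment_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      c(list(config_hash = report$config_hash,
             master_seed = report$master_seed), summary),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(per_beam, file.path(config$out_dir, "per_beam.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(config),
                         file.path(config$out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("experiment_report: arm '%s', seed %d, %d test beams (%.1f s)\n",
              s$arm, x$master_seed, s$n_test_beams, x$wall_time_s))
  cat(sprintf("  gamma(3%%/3mm)  DL %5.1f%%   PB %5.1f%%\n",
              s$mean_gamma_dl, s$mean_gamma_pb))
  cat(sprintf("  MAE (GyRBE)    DL %6.3f   PB %6.3f\n",
              s$mean_mae_dl, s$mean_mae_pb))
  cat(sprintf("  ARD R90 (%%)    DL %6.2f   PB %6.2f\n",
              s$mean_ard_r90_dl, s$mean_ard_r90_pb))
  invisible(x)
}

#' Compare ablation arms
#'
#' Paired per-beam deltas and mean +/- SD for each metric across arm
#' reports computed on the same test beams, plus the PB reference row.
#'
#' @param reports named list of `experiment_report`s (e.g. baseline,
#'   rotation, rotation_zoom) over identical test sets.
#' @return list with `table` (mean +/- SD per arm and metric, including a
#'   PB row) and `deltas` (per-beam DL - PB differences per arm).
#' @export
compare_arms <- function(reports) {
  if (length(reports) < 1) stop("need at least one report")
  ids <- lapply(reports, function(r) r$per_beam$id)
  if (!all(vapply(ids, identical, TRUE, ids[[1]])))
    stop("reports cover different test beams")
  if (is.null(names(reports)))
    names(reports) <- vapply(reports, function(r) r$summary$arm, "")
  msd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  pb <- reports[[1]]$per_beam
  table <- rbind(
    data.frame(arm = "pb", t(msd(pb$gamma_pb)), metric = "gamma",
               check.names = FALSE),
    do.call(rbind, lapply(names(reports), function(nm)
      data.frame(arm = nm, t(msd(reports[[nm]]$per_beam$gamma_dl)),
                 metric = "gamma", check.names = FALSE))),
    data.frame(arm = "pb", t(msd(pb$mae_pb)), metric = "mae",
               check.names = FALSE),
    do.call(rbind, lapply(names(reports), function(nm)
      data.frame(arm = nm, t(msd(reports[[nm]]$per_beam$mae_dl)),
                 metric = "mae", check.names = FALSE))),
    data.frame(arm = "pb", t(msd(pb$ard_r90_pb)), metric = "ard_r90",
               check.names = FALSE),
    do.call(rbind, lapply(names(reports), function(nm)
      data.frame(arm = nm, t(msd(reports[[nm]]$per_beam$ard_r90_dl)),
                 metric = "ard_r90", check.names = FALSE))))
  deltas <- lapply(reports, function(r)
    data.frame(id = r$per_beam$id,
               d_gamma = r$per_beam$gamma_dl - r$per_beam$gamma_pb,
               d_mae = r$per_beam$mae_dl - r$per_beam$mae_pb))
  list(table = table, deltas = deltas)
}
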