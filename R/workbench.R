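# Workbench: file formats, experiment presets, and the end-to-end
# pipeline tying cohort simulation, codec, diffusion, control, auxiliary
# models, prediction and evaluation into one reproducible run.

#' Write a 3D array as NIfTI-1
#' @param image 3D array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  RNifti::writeNifti(RNifti::asNifti(image), path)
  invisible(path)
}

#' Read a NIfTI file as a plain 3D array
#' @param path Input path.
#' @return 3D numeric array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI at ", path, ": ",
                                           conditionMessage(e)))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  a
}

#' Read and validate a covariate CSV
#'
#' Requires the standard columns (`subject_id`, `age`, `sex`,
#' `diagnosis`, `image`, `labels`, and the five `vol_*` columns); a
#' missing column is reported by name.
#'
#' @param path CSV path.
#' @return data.frame of visit records.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("no such covariate file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "diagnosis", "image", "labels",
            paste0("vol_", ALL_REGIONS))
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("covariate file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' Write / read a latent container
#'
#' Stores the latent values, their grid shape and the codec version id so
#' that stale latents cannot silently be mixed across codecs.
#'
#' @param latent 4D latent array.
#' @param path Output path (`.rds`).
#' @param codec_version Codec version id string.
#' @return `path` invisibly / the latent array with a
#'   `codec_version` attribute.
#' @export
write_latent <- function(latent, path, codec_version = "unversioned") {
  stopifnot(length(dim(latent)) == 4)
  saveRDS(list(values = as.vector(latent), shape = dim(latent),
               codec_version = codec_version), path)
  invisible(path)
}

#' @rdname write_latent
#' @export
read_latent <- function(path) {
  obj <- readRDS(path)
  stopifnot(all(c("values", "shape", "codec_version") %in% names(obj)))
  out <- array(obj$values, dim = obj$shape)
  attr(out, "codec_version") <- obj$codec_version
  out
}

# --- experiment configuration ----------------------------------------------

#' Experiment presets
#'
#' `desk_config()` is the small-scale configuration exercised end-to-end
#' on phantoms: 32x40x32 images, 2x4x5x4 latents, T = 1000 with the
#' scaled-linear beta schedule in `[0.0015, 0.0205]`, 25 DDIM steps and
#' m = 8. `paper_config()` pins the published full-scale settings
#' (122x146x122 images, 3x16x20x16 latents, m = 64); it is a
#' configuration contract, not something trainable at desk scale.
#'
#' @param seed Global seed; all stage seeds derive from it.
#' @param n_train,n_test Cohort sizes (desk preset).
#' @return Object of class `experiment_config`.
#' @export
desk_config <- function(seed = 1L, n_train = 60L, n_test = 30L) {
  grid <- c(32L, 40L, 32L)
  cfg <- list(
    preset = "desk",
    seed = as.integer(seed),
    grid_shape = grid,
    latent_shape = c(2L, 4L, 5L, 4L),
    n_train = as.integer(n_train),
    n_test = as.integer(n_test),
    visits_per_subject = 6L,
    age_range = c(60, 85),
    followup_years = 5,
    horizon_years = c(2, 5, 8),
    T = 1000L, beta_start = 0.0015, beta_end = 0.0205,
    ddim_steps = 25L, m = 8L,
    codec_epochs = 20L,
    ldm_steps = 12000L, control_steps = 20000L,
    hidden = c(256L, 256L),
    batch = 64L, lr = 2e-3
  )
  cfg$hash <- obj_hash(cfg)
  structure(cfg, class = "experiment_config")
}

#' @rdname desk_config
#' @export
paper_config <- function(seed = 1L) {
  cfg <- list(
    preset = "paper",
    seed = as.integer(seed),
    grid_shape = c(122L, 146L, 122L),
    latent_shape = c(3L, 16L, 20L, 16L),
    T = 1000L, beta_start = 0.0015, beta_end = 0.0205,
    ddim_steps = 25L, m = 64L,
    age_range = c(40, 100)
  )
  cfg$hash <- obj_hash(cfg)
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys: `preset` (`"desk"`, default, or `"paper"`), `seed`,
#' and for the desk preset `n_train`, `n_test`; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_config` (see [desk_config()]).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "desk"
  known <- c("preset", "seed", "n_train", "n_test")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (preset == "paper") {
    paper_config(seed = y$seed %||% 1L)
  } else if (preset == "desk") {
    desk_config(seed = y$seed %||% 1L,
                n_train = y$n_train %||% 60L,
                n_test = y$n_test %||% 30L)
  } else {
    stop("unknown preset: ", preset)
  }
}

stage_cached <- function(out_dir, name, cfg_hash, fn) {
  if (is.null(out_dir)) return(fn())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, "_", cfg_hash, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  obj <- fn()
  saveRDS(obj, path)
  obj
}

# --- end-to-end pipeline ----------------------------------------------------

#' Run the full desk-scale experiment
#'
#' Simulates a training and a held-out test cohort, trains the codec,
#' the conditional denoiser and the control network, fits the linear
#' auxiliary model, predicts multi-horizon follow-ups for every test
#' subject with LAS, and evaluates reconstruction quality, conditioning
#' fidelity, volumetric accuracy against the copy-forward baseline, the
#' distance-uncertainty trend and fast-progressor selection.
#'
#' @param config An [desk_config()] experiment configuration.
#' @param out_dir Optional directory for stage caching (content-keyed by
#'   the config hash; reruns with the same config reuse cached stages).
#' @param verbose Print stage progress.
#' @return Object of class `eval_report`; the trained models are
#'   attached as `$models`.
#' @export
run_pipeline <- function(config = desk_config(), out_dir = NULL,
                         verbose = interactive()) {
  stopifnot(inherits(config, "experiment_config"))
  if (!identical(config$preset, "desk")) {
    stop("run_pipeline executes the desk preset; preset '", config$preset,
         "' is a configuration contract only")
  }
  say <- function(...) if (verbose) message(...)
  seed <- config$seed
  spec <- phantom_spec(grid_shape = config$grid_shape)

  say("stage 1/7: simulating cohorts")
  train <- stage_cached(out_dir, "cohort_train", config$hash, function() {
    simulate_cohort(config$n_train, config$visits_per_subject,
                    age_range = config$age_range, spec = spec,
                    seed = derive_seed(seed, "train_cohort"))
  })
  test <- stage_cached(out_dir, "cohort_test", config$hash, function() {
    simulate_cohort(config$n_test, 2, age_range = config$age_range,
                    spec = spec, seed = derive_seed(seed, "test_cohort"),
                    visit_interval = config$followup_years)
  })

  say("stage 2/7: training codec")
  codec <- stage_cached(out_dir, "codec", config$hash, function() {
    train_codec(train$images,
                codec_config(config$grid_shape,
                             latent_shape = config$latent_shape,
                             epochs = config$codec_epochs,
                             seed = derive_seed(seed, "codec")))
  })

  say("stage 3/7: encoding latents")
  norm <- fit_covariate_norm(train$table,
                             age_range = config$age_range + c(0, 10))
  Z <- encode_matrix(codec, train$images)
  covs <- covariate_matrix(train$table$age, train$table$sex,
                           train$table$diagnosis,
                           cohort_volume_matrix(train$table), norm)
  schedule <- make_schedule(config$T, config$beta_start, config$beta_end)

  say("stage 4/7: training denoiser")
  denoiser <- stage_cached(out_dir, "denoiser", config$hash, function() {
    train_denoiser(Z, covs, schedule,
                   denoiser_config(ncol(Z), ncol(covs),
                                   hidden = config$hidden,
                                   steps = config$ldm_steps,
                                   batch = config$batch, lr = config$lr,
                                   seed = derive_seed(seed, "ldm")))
  })

  say("stage 5/7: training control network")
  control <- stage_cached(out_dir, "control", config$hash, function() {
    pairs <- make_training_pairs(train, codec, norm)
    ctl <- make_control(denoiser,
                        cond_dim = (config$latent_shape[1] + 1) *
                          prod(config$latent_shape[2:4]))
    train_control(ctl, pairs, schedule, steps = config$control_steps,
                  batch = config$batch, lr = config$lr,
                  seed = derive_seed(seed, "control"))
  })

  say("stage 6/7: fitting auxiliary model")
  aux <- fit_linear_aux(train$table)
  models <- progression_models(codec, control, aux, schedule, norm,
                               n_steps = config$ddim_steps)

  say("stage 7/7: predicting held-out follow-ups")
  tt <- test$table
  subj <- unique(tt$subject_id)
  recon_ssim <- numeric(0)
  per_subject <- list()
  rows_sel <- list()
  pred_mse <- numeric(0); pred_ssim <- numeric(0)
  mae_pred <- list(); mae_copy <- list()
  req_vent <- numeric(0); meas_vent <- numeric(0)
  for (sid in subj) {
    idx <- which(tt$subject_id == sid)
    idx <- idx[order(tt$age[idx])]
    base_i <- idx[1]; fu_i <- idx[2]
    x_A <- test$images[[base_i]]
    input_row <- tt[base_i, , drop = FALSE]
    recon_ssim <- c(recon_ssim, ssim3d(decode(codec, encode(codec, x_A)), x_A))

    dB_fu <- tt$age[fu_i] - tt$age[base_i]
    horizons <- sort(unique(c(config$horizon_years, dB_fu)))
    preds <- lapply(horizons, function(h) {
      las_predict(x_A, input_row, tt$age[base_i] + h, models,
                  m = config$m, seed = derive_seed(seed, paste0(sid, "_h", h)))
    })
    names(preds) <- paste0("h", horizons)
    per_subject[[sid]] <- preds

    p_fu <- preds[[paste0("h", dB_fu)]]
    v_meas <- measure_volumes_image(p_fu$image, spec)
    v_true <- cohort_volume_matrix(tt[fu_i, , drop = FALSE])[1, ]
    v_base <- cohort_volume_matrix(input_row)[1, ]
    mae_pred[[sid]] <- abs(v_meas[ALL_REGIONS] - v_true[ALL_REGIONS])
    mae_copy[[sid]] <- abs(v_base[ALL_REGIONS] - v_true[ALL_REGIONS])
    req_vent <- c(req_vent, p_fu$vhat[["ventricle"]])
    meas_vent <- c(meas_vent, v_meas[["ventricle"]])
    pred_mse <- c(pred_mse, mse(p_fu$image, test$images[[fu_i]]))
    pred_ssim <- c(pred_ssim, ssim3d(p_fu$image, test$images[[fu_i]]))
    rows_sel[[sid]] <- data.frame(
      subject_id = sid, v_A = v_base[["hippocampus"]],
      v_B_pred = v_meas[["hippocampus"]], v_B_true = v_true[["hippocampus"]]
    )
  }
  mae_pred <- do.call(rbind, mae_pred)
  mae_copy <- do.call(rbind, mae_copy)
  trend <- distance_uncertainty_trend(per_subject)
  sel <- select_fast_progressors(do.call(rbind, rows_sel),
                                 S = max(2L, length(subj) %/% 3))
  ct <- stats::cor.test(req_vent, meas_vent, method = "spearman", exact = FALSE)

  report <- list(
    config = config,
    n_train = length(unique(train$table$subject_id)),
    n_test = length(subj),
    codec_ssim = mean(recon_ssim),
    codec_ssim_sd = stats::sd(recon_ssim),
    pred_mse = mean(pred_mse), pred_ssim = mean(pred_ssim),
    ventricle_spearman = unname(ct$estimate),
    ventricle_spearman_p = ct$p.value,
    mae_pred = colMeans(mae_pred),
    mae_copy = colMeans(mae_copy),
    distance_uncertainty_rho = trend$rho,
    fast_progressor_overlap = sel$overlap,
    fast_progressor_S = length(sel$selected),
    predictions = per_subject,
    models = models,
    cohorts = list(train = train, test = test)
  )
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("end-to-end evaluation (", x$n_train, " train / ", x$n_test,
      " test subjects)\n", sep = "")
  cat(sprintf("  codec round-trip SSIM: %.3f\n", x$codec_ssim))
  cat(sprintf("  follow-up prediction:  MSE %.4g, SSIM %.3f\n",
              x$pred_mse, x$pred_ssim))
  cat(sprintf("  requested vs measured ventricle: Spearman %.3f (p = %.3g)\n",
              x$ventricle_spearman, x$ventricle_spearman_p))
  cat(sprintf("  ventricle MAE: prediction %.3f vs copy-forward %.3f\n",
              x$mae_pred[["ventricle"]], x$mae_copy[["ventricle"]]))
  cat(sprintf("  uncertainty vs distance: pooled Spearman %.3f\n",
              x$distance_uncertainty_rho))
  cat(sprintf("  fast-progressor overlap (S = %d): %.2f\n",
              x$fast_progressor_S, x$fast_progressor_overlap))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  keep <- report[c("n_train", "n_test", "codec_ssim", "pred_mse", "pred_ssim",
                   "ventricle_spearman", "ventricle_spearman_p",
                   "distance_uncertainty_rho", "fast_progressor_overlap",
                   "fast_progressor_S")]
  keep$mae_pred <- as.list(report$mae_pred)
  keep$mae_copy <- as.list(report$mae_copy)
  keep$config_hash <- report$config$hash
  keep$seed <- report$config$seed
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
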