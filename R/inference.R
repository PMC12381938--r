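# Inference: predict a subject's future brain image from one input scan.
#
# Six steps: (i) forecast the progression-related volumes at the target
# age with the auxiliary model; (ii) assemble the target covariates;
# (iii) encode the input image; (iv) draw terminal noise; (v) run the
# reverse diffusion with the anatomy-controlled denoiser; (vi) decode.
# Latent average stabilization (LAS) repeats (iv)-(v) m times from
# independent noise, averages the latents before decoding, and derives
# global and voxel-wise uncertainty from the spread of the m samples.

#' Bundle of trained models required for inference
#'
#' @param codec A trained [train_codec()] object.
#' @param control A trained [train_control()] model (wraps the frozen
#'   denoiser).
#' @param aux An auxiliary volume forecaster (see [predict_volumes()]).
#' @param schedule The [make_schedule()] used in training.
#' @param norm The [covariate_norm()] used in training.
#' @param n_steps Default number of DDIM steps.
#' @return Object of class `progression_models`.
#' @export
progression_models <- function(codec, control, aux, schedule, norm,
                               n_steps = 25) {
  structure(list(codec = codec, control = control, aux = aux,
                 schedule = schedule, norm = norm, n_steps = n_steps),
            class = "progression_models")
}

target_covariates <- function(models, input_row, B, vhat,
                              status_override = NULL) {
  status <- status_override %||% input_row$diagnosis
  vol <- stats::setNames(rep(NA_real_, length(ALL_REGIONS)), ALL_REGIONS)
  vol[names(vhat)] <- vhat
  # regions not forecast by the auxiliary model carry forward
  obs <- cohort_volume_matrix(input_row)[1, ]
  miss <- is.na(vol)
  vol[miss] <- obs[names(vol)[miss]]
  covariate_matrix(B, input_row$sex, status, vol, models$norm)
}

#' One inference pass from a single noise draw
#'
#' @param x_A Input 3D image at age A.
#' @param input_row One-row data.frame of the input visit covariates
#'   (`age`, `sex`, `diagnosis`, `vol_*`).
#' @param B Target age in years, `B > A`.
#' @param models A [progression_models()] bundle.
#' @param z_T Terminal noise (vector/array of latent length).
#' @param n_steps DDIM steps (default from `models`).
#' @param status_override Optional cognitive status used at the target in
#'   place of the input status (miscue experiments).
#' @param aux Optional auxiliary model overriding `models$aux`.
#' @return Predicted latent (vector of latent length).
#' @export
infer_once <- function(x_A, input_row, B, models, z_T, n_steps = NULL,
                       status_override = NULL, aux = NULL) {
  stopifnot(inherits(models, "progression_models"), nrow(input_row) == 1)
  if (B <= input_row$age) {
    stop("target age B = ", B, " must exceed the input age A = ", input_row$age)
  }
  aux <- aux %||% models$aux
  if (is.null(aux)) stop("no auxiliary model available")
  n_steps <- n_steps %||% models$n_steps
  vhat <- predict_volumes(aux, input_row, B)
  covB <- target_covariates(models, input_row, B, vhat, status_override)
  z_A <- encode(models$codec, x_A)
  cond <- as.vector(build_condition(z_A, input_row$age, models$norm))
  drop(ddim_sample(models$control, matrix(as.vector(z_T), 1), covB,
                   models$schedule, n_steps, matrix(cond, 1)))
}

#' Latent average stabilization prediction
#'
#' Runs the inference process `m` times from independent standard-normal
#' terminal noise (streamed from `seed`), averages the latents to
#' estimate the prediction mean, and derives uncertainty: the
#' per-element sample standard deviation (divisor m - 1), its overall
#' mean as the scalar global uncertainty, and the voxel-wise variance of
#' the decoded samples around the decoded mean as the uncertainty map.
#' The decoded prediction is the decode of the mean latent.
#'
#' @inheritParams infer_once
#' @param m Number of inference repetitions (>= 1).
#' @param seed Integer seed for the noise draws.
#' @param keep_samples Keep the m per-sample latents for audit.
#' @return Object of class `prediction_result` with fields `B`, `m`,
#'   `mu` (mean latent grid), `sigma` (per-element sd), `u` (global
#'   uncertainty scalar), `U` (voxel variance map), `image` (decoded
#'   prediction), `vhat` (forecast volumes), `seed`.
#' @export
las_predict <- function(x_A, input_row, B, models, m = 8, seed = 1L,
                        n_steps = NULL, status_override = NULL, aux = NULL,
                        keep_samples = FALSE) {
  stopifnot(inherits(models, "progression_models"), nrow(input_row) == 1)
  if (m < 1) stop("m must be >= 1")
  if (B <= input_row$age) {
    stop("target age B = ", B, " must exceed the input age A = ", input_row$age)
  }
  aux <- aux %||% models$aux
  if (is.null(aux)) stop("no auxiliary model available")
  n_steps <- n_steps %||% models$n_steps
  latent_dim <- models$codec$config$latent_dim
  lshape <- models$codec$config$latent_shape

  vhat <- predict_volumes(aux, input_row, B)
  covB <- target_covariates(models, input_row, B, vhat, status_override)
  z_A <- encode(models$codec, x_A)
  cond <- as.vector(build_condition(z_A, input_row$age, models$norm))

  ZT <- with_seed(derive_seed(seed, paste0("las_B", format(B))), {
    matrix(stats::rnorm(m * latent_dim), m, latent_dim)
  })
  # the m chains are independent; the batched run is elementwise
  # identical to running them sequentially
  Z <- ddim_sample(models$control, ZT, covB, models$schedule, n_steps,
                   matrix(cond, 1))
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  summarize_las(Z, models$codec, B, vhat, seed, keep_samples,
                input_age = input_row$age)
}

# shared LAS summary: also used with stubbed samplers/decoders in tests
summarize_las <- function(Z, codec, B, vhat = NULL, seed = NA_integer_,
                          keep_samples = FALSE, input_age = NA_real_,
                          decoder = NULL) {
  m <- nrow(Z)
  dec <- decoder %||% function(z) decode(codec, z)
  mu <- colMeans(Z)
  if (m > 1) {
    sigma <- sqrt(colSums(sweep(Z, 2, mu)^2) / (m - 1))
    u <- mean(sigma)
  } else {
    sigma <- rep(NA_real_, ncol(Z))
    u <- NA_real_
  }
  x_mu <- dec(mu)
  if (m > 1) {
    U <- 0 * x_mu
    for (i in seq_len(m)) U <- U + (dec(Z[i, ]) - x_mu)^2
    U <- U / (m - 1)
  } else {
    U <- NA
  }
  lshape <- if (!is.null(codec)) codec$config$latent_shape else c(ncol(Z), 1, 1, 1)
  structure(list(
    B = B, input_age = input_age, m = m,
    mu = array(mu, dim = lshape),
    sigma = array(sigma, dim = lshape),
    u = u, U = U, image = x_mu, vhat = vhat, seed = seed,
    uncertainty_available = m > 1,
    samples = if (keep_samples) Z else NULL
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction at age %.1f (m = %d): global uncertainty u = %s\n",
              x$B, x$m,
              if (x$uncertainty_available) sprintf("%.4g", x$u) else "n/a (m = 1)"))
  if (!is.null(x$vhat)) {
    cat("forecast volumes (% of brain):",
        paste(sprintf("%s=%.3g", names(x$vhat), x$vhat), collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict a series of follow-ups from one input visit
#'
#' Each target age is predicted independently from the same input image
#' (non-autoregressive). In `single_image` mode the bundled linear
#' auxiliary model forecasts the volumes; in `sequence_aware` mode a
#' logistic disease-course model is calibrated on the supplied visit
#' history (>= 2 visits) and used instead. Unordered target ages are
#' sorted with a warning.
#'
#' @param images List of the subject's past images (chronological); the
#'   last one is the inference input.
#' @param history data.frame of the subject's past visit covariates
#'   (same order as `images`).
#' @param target_ages Numeric vector of target ages.
#' @param models A [progression_models()] bundle.
#' @param mode `"single_image"` or `"sequence_aware"`.
#' @param m LAS repetitions per target age.
#' @param seed Integer seed.
#' @param course_prior Population prior for `sequence_aware` mode
#'   (default `models$course_prior` or [default_course_prior()]).
#' @param ... Passed to [las_predict()].
#' @return List of `prediction_result`, one per target age.
#' @export
predict_series <- function(images, history, target_ages, models,
                           mode = c("single_image", "sequence_aware"),
                           m = 8, seed = 1L, course_prior = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(length(images) == nrow(history))
  if (is.unsorted(target_ages)) {
    warning("target ages were unordered; sorting ascending")
    target_ages <- sort(target_ages)
  }
  ord <- order(history$age)
  history <- history[ord, , drop = FALSE]
  images <- images[ord]
  input_row <- history[nrow(history), , drop = FALSE]
  x_A <- images[[length(images)]]
  aux <- if (mode == "sequence_aware") {
    if (nrow(history) < 2) stop("sequence_aware mode requires >= 2 past visits")
    prior <- course_prior %||% models$course_prior %||% default_course_prior()
    fit_course_model(history, prior)
  } else {
    models$aux
  }
  lapply(seq_along(target_ages), function(i) {
    las_predict(x_A, input_row, target_ages[i], models, m = m,
                seed = derive_seed(seed, paste0("series", i)),
                aux = aux, ...)
  })
}
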