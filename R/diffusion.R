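# Diffusion core: noise schedule, forward diffusion, the noise-prediction
# training objective, and deterministic DDIM sampling.
#
# The denoiser is a small dense network with hand-written
# forward/backward passes and an Adam optimizer: it takes the flattened
# noisy latent, a sinusoidal timestep embedding and the covariate vector
# by concatenation, and predicts the injected noise.

#' Build a diffusion noise schedule
#'
#' The scaled-linear kind interpolates sqrt(beta) linearly:
#' `beta_t = (sqrt(beta_1) + (t-1)/(T-1) * (sqrt(beta_T) - sqrt(beta_1)))^2`,
#' with exact endpoints. `alpha_bar` is the cumulative product of
#' `1 - beta`.
#'
#' @param T_steps Number of diffusion steps T (>= 1).
#' @param beta_1,beta_T Endpoint variances in (0, 1), `beta_1 <= beta_T`.
#' @param kind `"scaled_linear"` (default) or `"linear"`.
#' @return Object of class `noise_schedule` with `T`, `beta`, `alpha`,
#'   `alpha_bar`.
#' @export
make_schedule <- function(T_steps = 1000, beta_1 = 0.0015, beta_T = 0.0205,
                          kind = c("scaled_linear", "linear")) {
  kind <- match.arg(kind)
  stopifnot(T_steps >= 1, beta_1 > 0, beta_T < 1, beta_1 <= beta_T)
  if (T_steps == 1) {
    if (beta_1 != beta_T) {
      stop("T = 1 with beta_1 != beta_T: interpolation undefined")
    }
    beta <- beta_1
  } else {
    frac <- (seq_len(T_steps) - 1) / (T_steps - 1)
    beta <- switch(kind,
      scaled_linear = (sqrt(beta_1) + frac * (sqrt(beta_T) - sqrt(beta_1)))^2,
      linear = beta_1 + frac * (beta_T - beta_1)
    )
  }
  structure(list(T = as.integer(T_steps), beta = beta, alpha = 1 - beta,
                 alpha_bar = cumprod(1 - beta), kind = kind),
            class = "noise_schedule")
}

#' Forward diffusion at step t
#'
#' `z_t = sqrt(alpha_bar_t) z_0 + sqrt(1 - alpha_bar_t) eps`; `t = 0`
#' returns `z_0` unchanged.
#'
#' @param z0 Latent array/matrix/vector.
#' @param t Integer step in `0..T`.
#' @param eps Noise with the same shape as `z0`.
#' @param schedule A [make_schedule()] object.
#' @return Noised latent with the shape of `z0`.
#' @export
forward_diffuse <- function(z0, t, eps, schedule) {
  stopifnot(inherits(schedule, "noise_schedule"))
  if (t == 0) return(z0)
  if (t < 0 || t > schedule$T) stop("t out of range [0, ", schedule$T, "]: ", t)
  if (!identical(length(z0), length(eps))) stop("eps shape does not match z0")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * z0 + sqrt(1 - ab) * eps
}

# --- covariates -------------------------------------------------------------

#' Covariate normalization parameters
#'
#' Age is min-max normalized over a configured range; region volumes are
#' standardized by training-set mean and sd.
#'
#' @param age_range Length-2 age range in years.
#' @param vol_mean,vol_sd Named per-region mean/sd of volumes (% of brain).
#' @return Object of class `covariate_norm`.
#' @export
covariate_norm <- function(age_range = c(40, 100),
                           vol_mean = stats::setNames(rep(0, 5), ALL_REGIONS),
                           vol_sd = stats::setNames(rep(1, 5), ALL_REGIONS)) {
  stopifnot(length(age_range) == 2, age_range[2] > age_range[1])
  structure(list(age_range = age_range,
                 vol_mean = vol_mean[ALL_REGIONS], vol_sd = vol_sd[ALL_REGIONS]),
            class = "covariate_norm")
}

#' Fit covariate normalization from a cohort table
#' @param table Cohort covariate data.frame (`vol_*` columns).
#' @param age_range Age normalization range (defaults to the generator's
#'   simulated range padded by the forecasting horizon).
#' @return A [covariate_norm()] object.
#' @export
fit_covariate_norm <- function(table, age_range = NULL) {
  vols <- cohort_volume_matrix(table)
  if (is.null(age_range)) {
    age_range <- range(table$age) + c(-2, 12)
  }
  covariate_norm(age_range = age_range,
                 vol_mean = colMeans(vols),
                 vol_sd = pmax(apply(vols, 2, stats::sd), 1e-8))
}

cohort_volume_matrix <- function(table) {
  cols <- paste0("vol_", ALL_REGIONS)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("covariate table missing column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(table[, cols])
  colnames(m) <- ALL_REGIONS
  m
}

normalize_age <- function(age, norm) {
  (age - norm$age_range[1]) / (norm$age_range[2] - norm$age_range[1])
}

#' Build the covariate vector(s) for conditioning
#'
#' Layout: normalized age, one-hot sex (F, M), one-hot cognitive status
#' (CN, MCI, AD), standardized volumes of the five tracked regions.
#'
#' @param age Age(s) in years.
#' @param sex `"F"`/`"M"` (recycled).
#' @param diagnosis `"CN"`/`"MCI"`/`"AD"` (recycled).
#' @param volumes Named vector or matrix (rows = samples) of region
#'   volumes (% of brain).
#' @param norm A [covariate_norm()] object.
#' @return Matrix `n x 11` of conditioning covariates.
#' @export
covariate_matrix <- function(age, sex, diagnosis, volumes, norm) {
  stopifnot(inherits(norm, "covariate_norm"))
  n <- length(age)
  if (is.null(dim(volumes))) volumes <- matrix(volumes, n, length(volumes),
                                               byrow = TRUE,
                                               dimnames = list(NULL, names(volumes)))
  stopifnot(all(ALL_REGIONS %in% colnames(volumes)))
  sex <- rep_len(sex, n); diagnosis <- rep_len(diagnosis, n)
  stopifnot(all(sex %in% c("F", "M")), all(diagnosis %in% c("CN", "MCI", "AD")))
  vstd <- sweep(sweep(volumes[, ALL_REGIONS, drop = FALSE], 2, norm$vol_mean),
                2, norm$vol_sd, "/")
  if (any(!is.finite(vstd))) stop("non-finite standardized volumes")
  cbind(age = normalize_age(age, norm),
        sexF = as.numeric(sex == "F"), sexM = as.numeric(sex == "M"),
        dxCN = as.numeric(diagnosis == "CN"),
        dxMCI = as.numeric(diagnosis == "MCI"),
        dxAD = as.numeric(diagnosis == "AD"),
        vstd)
}

covariate_row_from_table <- function(row, norm) {
  covariate_matrix(row$age, row$sex, row$diagnosis,
                   cohort_volume_matrix(row), norm)
}

# --- timestep embedding -----------------------------------------------------

timestep_embedding <- function(t, dim = 32L) {
  half <- dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(t, freqs)
  cbind(sin(ang), cos(ang))
}

# --- dense network with manual backprop ------------------------------------

mlp_init <- function(sizes, seed, zero_last = FALSE) {
  with_seed(seed, {
    L <- length(sizes) - 1
    net <- vector("list", L)
    for (l in seq_len(L)) {
      sdl <- if (zero_last && l == L) 0 else sqrt(2 / sizes[l])
      net[[l]] <- list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sdl),
                   sizes[l], sizes[l + 1]),
        b = numeric(sizes[l + 1])
      )
    }
    net
  })
}

# forward pass; hidden layers use SiLU, output is linear
mlp_forward <- function(net, X) {
  L <- length(net)
  pre <- vector("list", L)
  act <- vector("list", L + 1)
  act[[1]] <- X
  for (l in seq_len(L)) {
    pre[[l]] <- sweep(act[[l]] %*% net[[l]]$W, 2, net[[l]]$b, "+")
    act[[l + 1]] <- if (l < L) silu(pre[[l]]) else pre[[l]]
  }
  list(out = act[[L + 1]], pre = pre, act = act)
}

# returns parameter gradients and the gradient wrt the input
mlp_backward <- function(net, fw, dout) {
  L <- length(net)
  grads <- vector("list", L)
  d <- dout
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d * dsilu(fw$pre[[l]])
    grads[[l]] <- list(W = crossprod(fw$act[[l]], d), b = colSums(d))
    d <- d %*% t(net[[l]]$W)
  }
  list(grads = grads, dX = d)
}

# piecewise learning-rate decay: full rate for 60% of the run, then
# 1/4, then 1/10 for the final 15% (settles the least-squares tail)
lr_decay_factor <- function(step, total) {
  if (step <= 0.6 * total) 1 else if (step <= 0.85 * total) 0.25 else 0.1
}

adam_init <- function(net) {
  lapply(net, function(lay) list(
    mW = lay$W * 0, vW = lay$W * 0, mb = lay$b * 0, vb = lay$b * 0
  ))
}

adam_update <- function(net, grads, state, lr, step,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^step; c2 <- 1 - b2^step
  for (l in seq_along(net)) {
    st <- state[[l]]; g <- grads[[l]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    net[[l]]$W <- net[[l]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    net[[l]]$b <- net[[l]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[l]] <- st
  }
  list(net = net, state = state)
}

# --- denoiser ---------------------------------------------------------------

#' Denoiser configuration
#'
#' @param latent_dim Flattened latent length.
#' @param cov_dim Covariate vector length (11 for the standard layout).
#' @param hidden Two hidden-layer widths.
#' @param temb_dim Sinusoidal timestep-embedding dimension.
#' @param steps Number of Adam steps.
#' @param batch Minibatch size.
#' @param lr Learning rate.
#' @param seed Integer seed.
#' @return Object of class `denoiser_config`.
#' @export
denoiser_config <- function(latent_dim, cov_dim = 11L, hidden = c(192L, 192L),
                            temb_dim = 32L, steps = 4000L, batch = 64L,
                            lr = 2e-3, seed = 1L) {
  stopifnot(length(hidden) == 2)
  structure(list(latent_dim = as.integer(latent_dim), cov_dim = as.integer(cov_dim),
                 hidden = as.integer(hidden), temb_dim = as.integer(temb_dim),
                 steps = as.integer(steps), batch = as.integer(batch),
                 lr = lr, seed = as.integer(seed)),
            class = "denoiser_config")
}

denoiser_input <- function(model, zt, t, cov) {
  n <- nrow(zt)
  t <- rep_len(t, n)
  if (is.null(dim(cov))) {
    cov <- matrix(cov, n, length(cov), byrow = TRUE)
  } else if (nrow(cov) == 1 && n > 1) {
    cov <- cov[rep(1L, n), , drop = FALSE]
  }
  cbind(zt, timestep_embedding(t, model$config$temb_dim), cov)
}

#' Predict the injected noise
#'
#' Generic over denoiser models: the trained dense denoiser, the
#' control-extended model, or a plain function
#' `f(zt, t, cov, cond, schedule)` used for analytic oracles and stubs.
#'
#' @param model The noise predictor.
#' @param zt Matrix `n x latent_dim` of noisy latents (a vector is
#'   treated as one row).
#' @param t Integer timestep (scalar or length n).
#' @param cov Covariate matrix `n x cov_dim` (or single row).
#' @param cond Optional anatomy condition matrix `n x cond_dim`.
#' @param schedule The [make_schedule()] object in use.
#' @return Matrix `n x latent_dim` of predicted noise.
#' @export
predict_noise <- function(model, zt, t, cov = NULL, cond = NULL, schedule = NULL) {
  UseMethod("predict_noise")
}

#' @export
predict_noise.function <- function(model, zt, t, cov = NULL, cond = NULL,
                                   schedule = NULL) {
  model(zt, t, cov, cond, schedule)
}

#' @export
predict_noise.denoiser_mlp <- function(model, zt, t, cov = NULL, cond = NULL,
                                       schedule = NULL) {
  if (is.null(dim(zt))) zt <- matrix(zt, 1)
  z0hat <- mlp_forward(model$net, denoiser_input(model, zt, t, cov))$out
  x0_to_eps(model, z0hat, zt, t)
}

# The network predicts the clean latent (x0-parameterization); the
# exposed quantity is always the implied noise. Direct eps prediction is
# amplified by 1/sqrt(alpha_bar_t) at high t when converted back to a
# clean-latent estimate, which destabilizes few-step sampling; the
# x0 form keeps every sampling coefficient bounded.
x0_to_eps <- function(model, z0hat, zt, t) {
  t <- rep_len(t, nrow(zt))
  ab <- model$alpha_bar[t]
  (zt - sqrt(ab) * z0hat) / sqrt(1 - ab)
}

#' Monte-Carlo noise-prediction loss
#'
#' Samples `t ~ U{1..T}` and standard-normal noise per row of `z0`,
#' forms `z_t`, and returns the mean squared error between the injected
#' and predicted noise (mean over all elements).
#'
#' @param model A noise predictor (see [predict_noise()]).
#' @param z0 Matrix `n x latent_dim` of clean latents.
#' @param cov Covariate matrix (`n x cov_dim` or single row).
#' @param schedule A [make_schedule()] object.
#' @param seed Optional seed for the draw.
#' @return Scalar loss.
#' @export
denoise_loss <- function(model, z0, cov, schedule, seed = NULL) {
  if (is.null(dim(z0))) z0 <- matrix(z0, 1)
  draw <- function() {
    t <- sample.int(schedule$T, nrow(z0), replace = TRUE)
    eps <- matrix(stats::rnorm(length(z0)), nrow(z0))
    list(t = t, eps = eps)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  ab <- schedule$alpha_bar[d$t]
  zt <- sqrt(ab) * z0 + sqrt(1 - ab) * d$eps
  pred <- predict_noise(model, zt, d$t, cov, NULL, schedule)
  mean((d$eps - pred)^2)
}

#' Train the covariate-conditioned denoiser
#'
#' Minimizes the noise-prediction objective over uniformly sampled
#' timesteps with Adam. Internally the network predicts the clean latent
#' (x0-parameterization; the noise objective reweighted per timestep by
#' `(1 - alpha_bar_t) / alpha_bar_t`), with a zero-initialized output
#' layer; the model always exposes predicted noise through
#' [predict_noise()]. Aborts with a diagnostic on non-finite loss.
#'
#' @param latents Matrix `n x latent_dim` of (unit-scale) training latents.
#' @param covariates Matrix `n x cov_dim` from [covariate_matrix()].
#' @param schedule A [make_schedule()] object.
#' @param config A [denoiser_config()].
#' @return Object of class `denoiser_mlp` with the network and a loss log
#'   (running mean of the clean-latent loss over 50-step windows).
#' @export
train_denoiser <- function(latents, covariates, schedule, config) {
  stopifnot(inherits(config, "denoiser_config"),
            nrow(latents) >= 1,
            ncol(latents) == config$latent_dim,
            nrow(covariates) == nrow(latents),
            ncol(covariates) == config$cov_dim)
  in_dim <- config$latent_dim + config$temb_dim + config$cov_dim
  net <- mlp_init(c(in_dim, config$hidden, config$latent_dim),
                  derive_seed(config$seed, "denoiser_init"), zero_last = TRUE)
  model <- structure(list(net = net, config = config,
                          alpha_bar = schedule$alpha_bar),
                     class = "denoiser_mlp")
  st <- adam_init(net)
  n <- nrow(latents)
  log_win <- 50L
  losses <- numeric(0)
  acc <- 0
  with_seed(derive_seed(config$seed, "denoiser_train"), {
    for (step in seq_len(config$steps)) {
      idx <- sample.int(n, min(config$batch, n), replace = config$batch > n)
      z0 <- latents[idx, , drop = FALSE]
      t <- sample.int(schedule$T, length(idx), replace = TRUE)
      eps <- matrix(stats::rnorm(length(z0)), nrow(z0))
      ab <- schedule$alpha_bar[t]
      zt <- sqrt(ab) * z0 + sqrt(1 - ab) * eps
      target <- z0
      X <- denoiser_input(model, zt, t, covariates[idx, , drop = FALSE])
      fw <- mlp_forward(model$net, X)
      resid <- fw$out - target
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop("non-finite training loss at step ", step,
             " (lr too high or degenerate inputs)")
      }
      bw <- mlp_backward(model$net, fw, 2 * resid / length(resid))
      lr_now <- config$lr * lr_decay_factor(step, config$steps)
      up <- adam_update(model$net, bw$grads, st, lr_now, step)
      model$net <- up$net; st <- up$state
      acc <- acc + loss
      if (step %% log_win == 0) {
        losses <- c(losses, acc / log_win)
        acc <- 0
      }
    }
  })
  model$loss_log <- losses
  model
}

# --- DDIM sampling ----------------------------------------------------------

ddim_timesteps <- function(T_steps, n_steps) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (n_steps > T_steps) stop("n_steps must be <= T")
  if (n_steps == 1) return(T_steps)
  unique(floor(seq(T_steps, 1, length.out = n_steps)))
}

#' Deterministic DDIM sampling
#'
#' Runs the eta = 0 DDIM update over an evenly spaced decreasing
#' subsequence of `{1..T}` (including `T` and 1; interpolated values
#' rounded down). A pure function of its arguments: identical inputs give
#' identical outputs.
#'
#' @param model A noise predictor (see [predict_noise()]).
#' @param z_T Matrix `n x latent_dim` of terminal noise (vector = 1 row).
#' @param cov Covariate matrix (or single row), passed to the model.
#' @param schedule A [make_schedule()] object.
#' @param n_steps Number of denoising steps (1..T).
#' @param cond Optional anatomy condition passed to the model.
#' @param clip_z0 Range the implied clean latent is clipped to at every
#'   step (static thresholding; latents are unit-scale by construction).
#'   `NULL` disables clipping.
#' @return Matrix `n x latent_dim` of generated latents `z_0`.
#' @export
ddim_sample <- function(model, z_T, cov = NULL, schedule, n_steps = 25,
                        cond = NULL, clip_z0 = c(-6, 6)) {
  stopifnot(inherits(schedule, "noise_schedule"))
  one_row <- is.null(dim(z_T))
  z <- if (one_row) matrix(z_T, 1) else z_T
  taus <- ddim_timesteps(schedule$T, n_steps)
  ab <- schedule$alpha_bar
  for (i in seq_along(taus)) {
    t <- taus[i]
    eps <- predict_noise(model, z, t, cov, cond, schedule)
    z0hat <- (z - sqrt(1 - ab[t]) * eps) / sqrt(ab[t])
    if (!is.null(clip_z0)) {
      z0hat <- pmin(pmax(z0hat, clip_z0[1]), clip_z0[2])
      eps <- (z - sqrt(ab[t]) * z0hat) / sqrt(1 - ab[t])
    }
    ab_next <- if (i < length(taus)) ab[taus[i + 1]] else 1
    z <- sqrt(ab_next) * z0hat + sqrt(1 - ab_next) * eps
  }
  if (one_row) drop(z) else z
}
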