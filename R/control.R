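# Anatomy control network.
#
# A trainable copy of the denoiser's first (encoder) layer processes the
# same input plus the anatomy condition -- the subject's baseline latent
# z(A) with the normalized starting age appended as an extra constant
# channel. Its activations are injected back into the frozen denoiser
# after the first layer through a zero-initialized connector, so at
# initialization the combined model reproduces the frozen denoiser
# exactly, and the frozen parameters are never updated.

#' Build the anatomy condition from a baseline latent and starting age
#'
#' Appends one constant channel holding the min-max normalized starting
#' age to the latent grid, mirroring channel-axis concatenation.
#'
#' @param z_A 4D latent array `(channels, d, h, w)`.
#' @param age_A Starting age in years.
#' @param norm A [covariate_norm()] (supplies the age range).
#' @return 4D array `(channels + 1, d, h, w)`.
#' @export
build_condition <- function(z_A, age_A, norm) {
  stopifnot(length(dim(z_A)) == 4)
  d <- dim(z_A)
  out <- array(0, dim = c(d[1] + 1, d[2:4]))
  out[seq_len(d[1]), , , ] <- z_A
  out[d[1] + 1, , , ] <- normalize_age(age_A, norm)
  out
}

# flattened condition rows for a batch of latents (matrix n x latent_dim)
condition_matrix <- function(Z_A, ages, norm, latent_shape) {
  t(vapply(seq_len(nrow(Z_A)), function(i) {
    as.vector(build_condition(array(Z_A[i, ], dim = latent_shape), ages[i], norm))
  }, numeric((latent_shape[1] + 1) * prod(latent_shape[2:4]))))
}

#' Create a control model from a trained denoiser
#'
#' The returned model holds a frozen reference to the denoiser, a
#' trainable copy of its hidden (encoder) layers, a zero-initialized
#' condition input map and a zero-initialized output connector. The
#' connector maps the copy's activations together with the condition's
#' baseline latent and the frozen model's implied clean-latent estimate
#' into an additive correction of that estimate, so the anatomy-copy
#' solution is linearly reachable. The zero connector makes the combined
#' output exactly equal to the frozen denoiser's output at
#' initialization.
#'
#' @param denoiser A trained [train_denoiser()] model.
#' @param cond_dim Flattened condition length
#'   (`(latent_channels + 1) * prod(spatial dims)`).
#' @return Object of class `control_model`.
#' @export
make_control <- function(denoiser, cond_dim) {
  stopifnot(inherits(denoiser, "denoiser_mlp"), cond_dim >= 1)
  h1 <- ncol(denoiser$net[[1]]$W)
  h2 <- ncol(denoiser$net[[2]]$W)
  latent_dim <- denoiser$config$latent_dim
  s <- cond_dim - latent_dim
  ch <- latent_dim / s
  if (s < 1 || ch != round(ch)) {
    stop("cond_dim ", cond_dim, " is not latent_dim + spatial size for latent dim ",
         latent_dim)
  }
  # positions of the latent entries in the flattened (channels+1, ...)
  # condition (channel index varies fastest)
  idx_lat <- which(rep(seq_len(ch + 1), times = s) <= ch)
  structure(list(
    frozen = denoiser,
    W1c = denoiser$net[[1]]$W,
    b1c = denoiser$net[[1]]$b,
    W2c = denoiser$net[[2]]$W,
    b2c = denoiser$net[[2]]$b,
    Zin = matrix(0, cond_dim, h1),
    Zout = matrix(0, h2 + 4 * latent_dim + 2 * denoiser$config$cov_dim,
                  latent_dim),
    cond_dim = as.integer(cond_dim),
    idx_lat = idx_lat,
    config = denoiser$config
  ), class = "control_model")
}

control_forward <- function(model, zt, t, cov, cond) {
  if (is.null(dim(zt))) zt <- matrix(zt, 1)
  if (is.null(dim(cond))) {
    cond <- matrix(cond, nrow(zt), length(cond), byrow = TRUE)
  } else if (nrow(cond) == 1 && nrow(zt) > 1) {
    cond <- cond[rep(1L, nrow(zt)), , drop = FALSE]
  }
  X <- denoiser_input(model, zt, t, cov)
  net <- model$frozen$net
  h1f <- silu(sweep(X %*% net[[1]]$W, 2, net[[1]]$b, "+"))
  h2f <- silu(sweep(h1f %*% net[[2]]$W, 2, net[[2]]$b, "+"))
  z0f <- sweep(h2f %*% net[[3]]$W, 2, net[[3]]$b, "+")
  pre1c <- sweep(X %*% model$W1c + cond %*% model$Zin, 2, model$b1c, "+")
  h1c <- silu(pre1c)
  pre2c <- sweep(h1c %*% model$W2c, 2, model$b2c, "+")
  h2c <- silu(pre2c)
  # w(t) = 1 - alpha_bar_t lets the connector form timestep-interpolating
  # linear corrections: at low t the noisy latent dominates, at high t
  # the baseline anatomy does
  w <- 1 - model$frozen$alpha_bar[rep_len(t, nrow(zt))]
  cond_lat <- cond[, model$idx_lat, drop = FALSE]
  covm <- X[, model$config$latent_dim + model$config$temb_dim +
              seq_len(model$config$cov_dim), drop = FALSE]
  feats <- cbind(h2c, cond_lat, z0f, w * cond_lat, w * z0f, covm, w * covm)
  out <- z0f + feats %*% model$Zout
  list(out = out, X = X, cond = cond, pre1c = pre1c, h1c = h1c,
       pre2c = pre2c, h2c = h2c, feats = feats)
}

#' @export
predict_noise.control_model <- function(model, zt, t, cov = NULL, cond = NULL,
                                        schedule = NULL) {
  if (is.null(cond)) stop("control model requires an anatomy condition")
  if (is.null(dim(zt))) zt <- matrix(zt, 1)
  z0hat <- control_forward(model, zt, t, cov, cond)$out
  x0_to_eps(model$frozen, z0hat, zt, t)
}

# gradients of the loss wrt the trainable control parameters only;
# the frozen denoiser weights enter as constants
control_backward <- function(model, fw, dout) {
  h2_dim <- ncol(fw$h2c)
  dZout <- crossprod(fw$feats, dout)
  dh2c <- dout %*% t(model$Zout[seq_len(h2_dim), , drop = FALSE])
  dpre2c <- dh2c * dsilu(fw$pre2c)
  dh1c <- dpre2c %*% t(model$W2c)
  dpre1c <- dh1c * dsilu(fw$pre1c)
  list(W1c = crossprod(fw$X, dpre1c),
       b1c = colSums(dpre1c),
       W2c = crossprod(fw$h1c, dpre2c),
       b2c = colSums(dpre2c),
       Zin = crossprod(fw$cond, dpre1c),
       Zout = dZout)
}

#' Build control-training pairs from a cohort
#'
#' Uses all ordered same-subject visit pairs with `age_A < age_B` (k
#' visits yield k(k-1)/2 pairs). Pairs with non-increasing ages are
#' dropped with a warning count.
#'
#' @param cohort A [simulate_cohort()] object (or compatible list with
#'   `table` and `images`).
#' @param codec A trained [train_codec()] object used to encode visits.
#' @param norm A [covariate_norm()] object.
#' @param consecutive_only If `TRUE`, restrict to consecutive visit pairs.
#' @return List with matrices `Z_A`, `Z_B`, `cov_B`, vector `age_A`.
#' @export
make_training_pairs <- function(cohort, codec, norm, consecutive_only = FALSE) {
  tab <- cohort$table
  Z <- encode_matrix(codec, cohort$images)
  ia <- integer(0); ib <- integer(0)
  dropped <- 0L
  for (sid in unique(tab$subject_id)) {
    idx <- which(tab$subject_id == sid)
    idx <- idx[order(tab$age[idx])]
    k <- length(idx)
    if (k < 2) next
    for (a in seq_len(k - 1)) {
      bs <- if (consecutive_only) a + 1L else (a + 1L):k
      for (b in bs) {
        if (tab$age[idx[b]] <= tab$age[idx[a]]) { dropped <- dropped + 1L; next }
        ia <- c(ia, idx[a]); ib <- c(ib, idx[b])
      }
    }
  }
  if (dropped > 0) warning(dropped, " pair(s) with non-increasing ages dropped")
  cov_B <- covariate_matrix(tab$age[ib], tab$sex[ib], tab$diagnosis[ib],
                            cohort_volume_matrix(tab[ib, , drop = FALSE]), norm)
  ZA <- Z[ia, , drop = FALSE]
  list(Z_A = ZA, Z_B = Z[ib, , drop = FALSE],
       age_A = tab$age[ia], cov_B = cov_B,
       cond = condition_matrix(ZA, tab$age[ia], norm,
                               codec$config$latent_shape))
}

#' Train the control network
#'
#' Each iteration samples a timestep uniformly, forward-diffuses the
#' follow-up latent `z(B)`, predicts the noise with the combined model
#' conditioned on the target covariates `c(B)` and the baseline condition
#' `(z(A), A)`, and takes an Adam step on the noise-prediction loss over
#' the control parameters only. The frozen denoiser is never modified.
#'
#' @param control A [make_control()] model.
#' @param pairs Output of [make_training_pairs()].
#' @param schedule A [make_schedule()] object.
#' @param steps,batch,lr,seed Training hyperparameters.
#' @param weight_decay Decoupled weight decay on the control parameters.
#' @param nl_decay Additional decay on the connector rows fed by the
#'   nonlinear copy activations; biases the connector towards the
#'   generalizing linear anatomy/covariate paths.
#' @param cond_noise_sd Gaussian noise added to the condition during
#'   training (augmentation against overfitting subject anatomy).
#' @return The trained `control_model` with a `loss_log`.
#' @export
train_control <- function(control, pairs, schedule,
                          steps = 4000L, batch = 64L, lr = 2e-3, seed = 1L,
                          weight_decay = 1e-4, nl_decay = 3e-3,
                          cond_noise_sd = 0.05) {
  stopifnot(inherits(control, "control_model"), !is.null(pairs$cond))
  n <- nrow(pairs$Z_A)
  stopifnot(n >= 1)
  Cnd <- pairs$cond
  stopifnot(ncol(Cnd) == control$cond_dim)
  params <- list(W1c = control$W1c, b1c = control$b1c,
                 W2c = control$W2c, b2c = control$b2c,
                 Zin = control$Zin, Zout = control$Zout)
  nl_rows <- seq_len(control$config$hidden[2])
  st <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  log_win <- 50L
  losses <- numeric(0); acc <- 0
  with_seed(derive_seed(seed, "control_train"), {
    for (step in seq_len(steps)) {
      idx <- sample.int(n, min(batch, n), replace = batch > n)
      z0 <- pairs$Z_B[idx, , drop = FALSE]
      t <- sample.int(schedule$T, length(idx), replace = TRUE)
      eps <- matrix(stats::rnorm(length(z0)), nrow(z0))
      ab <- schedule$alpha_bar[t]
      zt <- sqrt(ab) * z0 + sqrt(1 - ab) * eps
      target <- z0
      model_now <- control
      for (nm in names(params)) model_now[[nm]] <- params[[nm]]
      cb <- Cnd[idx, , drop = FALSE]
      if (cond_noise_sd > 0) {
        cb <- cb + matrix(stats::rnorm(length(cb), 0, cond_noise_sd), nrow(cb))
      }
      fw <- control_forward(model_now, zt, t, pairs$cov_B[idx, , drop = FALSE],
                            cb)
      resid <- fw$out - target
      loss <- mean(resid^2)
      if (!is.finite(loss)) stop("non-finite control loss at step ", step)
      g <- control_backward(model_now, fw, 2 * resid / length(resid))
      c1 <- 1 - 0.9^step; c2 <- 1 - 0.999^step
      lr_now <- lr * lr_decay_factor(step, steps)
      for (nm in names(params)) {
        st[[nm]]$m <- 0.9 * st[[nm]]$m + 0.1 * g[[nm]]
        st[[nm]]$v <- 0.999 * st[[nm]]$v + 0.001 * g[[nm]]^2
        params[[nm]] <- params[[nm]] -
          lr_now * (st[[nm]]$m / c1) / (sqrt(st[[nm]]$v / c2) + 1e-8) -
          lr_now * weight_decay * params[[nm]]
        if (nm == "Zout" && nl_decay > 0) {
          params$Zout[nl_rows, ] <- params$Zout[nl_rows, ] *
            (1 - lr_now * nl_decay)
        }
      }
      acc <- acc + loss
      if (step %% log_win == 0) { losses <- c(losses, acc / log_win); acc <- 0 }
    }
  })
  for (nm in names(params)) control[[nm]] <- params[[nm]]
  control$loss_log <- losses
  control
}
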