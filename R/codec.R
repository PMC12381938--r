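# Latent codec: maps 3D images to compact latent grids and back.
#
# The codec is a linear Gaussian autoencoder (probabilistic-PCA style):
# decode(z) = W_d z + xbar, encode(x) = posterior mean of z given x under
# an isotropic noise model, i.e. the ridge solution
#   mu(x) = (W_d' W_d + kl_weight I)^-1 W_d' (x - xbar).
# Training minimizes mean reconstruction MSE + kl_weight * mean(mu^2) by
# alternating least squares; each sweep ("epoch") is a pair of exact
# minimizations, so the logged loss is non-increasing by construction.
# Latents are divided by a scalar scale (sd of training latent elements)
# so diffusion operates on approximately unit-scale data.

#' Codec configuration
#'
#' @param image_shape Integer vector of 3 voxel counts.
#' @param latent_channels Number of latent channels.
#' @param downsample Per-axis spatial downsampling factor; latent spatial
#'   dims default to `ceiling(image_shape / downsample)`.
#' @param latent_shape Optional explicit latent shape
#'   `(channels, d, h, w)`, overriding the ceil rule (used by presets).
#' @param kl_weight Non-negative weight of the latent prior term; acts as
#'   a ridge penalty on the posterior mean.
#' @param epochs Number of alternating-least-squares sweeps.
#' @param seed Integer seed for the decoder initialization.
#' @return An object of class `codec_config`.
#' @export
codec_config <- function(image_shape, latent_channels = 2, downsample = 8,
                         latent_shape = NULL, kl_weight = 1e-6,
                         epochs = 25, seed = 1L) {
  stopifnot(length(image_shape) == 3, all(image_shape >= 1), kl_weight >= 0,
            epochs >= 1)
  if (is.null(latent_shape)) {
    latent_shape <- c(latent_channels, ceiling(image_shape / downsample))
  }
  stopifnot(length(latent_shape) == 4)
  structure(list(image_shape = as.integer(image_shape),
                 latent_channels = as.integer(latent_shape[1]),
                 downsample = downsample,
                 latent_shape = as.integer(latent_shape),
                 latent_dim = as.integer(prod(latent_shape)),
                 kl_weight = kl_weight, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "codec_config")
}

#' Train the latent codec
#'
#' @param images List of 3D arrays with shape `config$image_shape`.
#' @param config A [codec_config()].
#' @return An object of class `latent_codec` with the decoder matrix,
#'   encoder matrix, training log and a version id.
#' @export
train_codec <- function(images, config) {
  stopifnot(inherits(config, "codec_config"), length(images) >= 2)
  p <- prod(config$image_shape)
  for (i in seq_along(images)) {
    di <- dim(images[[i]])
    if (is.null(di) || !all(di == config$image_shape)) {
      stop("image ", i, " has shape ", paste(di, collapse = "x"),
           ", expected ", paste(config$image_shape, collapse = "x"))
    }
  }
  n <- length(images)
  k <- config$latent_dim
  X <- matrix(0, p, n)
  for (i in seq_len(n)) X[, i] <- as.vector(images[[i]])
  xbar <- rowMeans(X)
  Xc <- X - xbar

  Wd <- with_seed(config$seed, matrix(stats::rnorm(p * k, 0, 1 / sqrt(p)), p, k))
  lam <- config$kl_weight
  jit <- 1e-10
  loss <- numeric(config$epochs)
  Z <- NULL
  for (e in seq_len(config$epochs)) {
    G <- crossprod(Wd) + diag(lam + jit, k)
    Z <- solve(G, crossprod(Wd, Xc))            # k x n codes (posterior means)
    H <- tcrossprod(Z) + diag(jit, k)
    Wd <- t(solve(H, Z %*% t(Xc)))              # p x k decoder
    R <- Xc - Wd %*% Z
    loss[e] <- mean(R^2) + lam * mean(Z^2)
  }
  # rotate the latent basis to principal axes so coordinates are
  # decorrelated and variance-ordered: signal concentrates in the
  # leading dims, which conditions the downstream diffusion model
  G <- crossprod(Wd) + diag(lam + jit, k)
  We <- solve(G, t(Wd))                          # k x p encoder
  Zfin <- We %*% Xc
  sv <- svd(Zfin, nu = k, nv = 0)
  rot <- sv$u                                    # k x k orthogonal
  We <- crossprod(rot, We)
  Wd <- Wd %*% rot
  Zfin <- crossprod(rot, Zfin)
  # per-element standardization: every latent coordinate enters the
  # diffusion model at unit scale
  scale <- apply(Zfin, 1, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  scale <- pmax(scale, 1e-6 * max(scale, 1))

  structure(list(Wd = Wd, We = We, xbar = xbar, latent_scale = scale,
                 config = config, loss = loss,
                 version = obj_hash(list(config, loss, scale))),
            class = "latent_codec")
}

#' Encode an image to a latent grid
#'
#' Returns the (deterministic) posterior mean latent, divided by the
#' training latent scale, reshaped to the configured latent grid.
#'
#' @param codec A trained [train_codec()] object.
#' @param image 3D array with the configured image shape.
#' @return 4D array `(channels, d, h, w)` of class-free numeric values.
#' @export
encode <- function(codec, image) {
  stopifnot(inherits(codec, "latent_codec"))
  di <- dim(image)
  if (is.null(di) || !all(di == codec$config$image_shape)) {
    stop("image shape ", paste(di, collapse = "x"), " does not match codec config ",
         paste(codec$config$image_shape, collapse = "x"))
  }
  z <- as.vector(codec$We %*% (as.vector(image) - codec$xbar)) / codec$latent_scale
  array(z, dim = codec$config$latent_shape)
}

#' Decode a latent grid to an image
#'
#' @param codec A trained [train_codec()] object.
#' @param latent 4D latent array (or vector of matching length).
#' @return 3D array with the configured image shape.
#' @export
decode <- function(codec, latent) {
  stopifnot(inherits(codec, "latent_codec"))
  z <- as.vector(latent)
  if (length(z) != codec$config$latent_dim) {
    stop("latent length ", length(z), " does not match codec config latent dim ",
         codec$config$latent_dim)
  }
  x <- as.vector(codec$Wd %*% (z * codec$latent_scale)) + codec$xbar
  array(x, dim = codec$config$image_shape)
}

# matrix versions used by training / LAS (rows = samples)
encode_matrix <- function(codec, images) {
  t(vapply(images, function(im) as.vector(encode(codec, im)),
           numeric(codec$config$latent_dim)))
}

decode_matrix <- function(codec, Z) {
  # Z: n x latent_dim; returns p x n matrix of flattened images
  codec$Wd %*% (t(Z) * codec$latent_scale) + codec$xbar  # recycles per-dim scale
}

#' @export
print.latent_codec <- function(x, ...) {
  cat("latent codec:", paste(x$config$image_shape, collapse = "x"), "->",
      paste(x$config$latent_shape, collapse = "x"),
      sprintf("(final loss %.3g, scale range %.3g-%.3g)\n",
              x$loss[length(x$loss)], min(x$latent_scale),
              max(x$latent_scale)))
  invisible(x)
}
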