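# Evaluation metrics: image similarity, volumetric accuracy, uncertainty
# analyses and the fast-progressor selection experiment.

#' Mean squared error between two images
#' @param a,b Arrays of identical shape.
#' @return Scalar MSE.
#' @export
mse <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  mean((a - b)^2)
}

# sliding box sum with "valid" extent along one axis of a 3D array
box_sum_axis <- function(a, w, axis) {
  d <- dim(a)
  nout <- d[axis] - w + 1
  idx <- function(off) {
    switch(axis,
           a[off + seq_len(nout), , , drop = FALSE],
           a[, off + seq_len(nout), , drop = FALSE],
           a[, , off + seq_len(nout), drop = FALSE])
  }
  out <- idx(0L)
  for (off in seq_len(w - 1)) out <- out + idx(off)
  out
}

box_mean3 <- function(a, w) {
  s <- box_sum_axis(box_sum_axis(box_sum_axis(a, w, 1L), w, 2L), w, 3L)
  s / w^3
}

#' 3D structural similarity index
#'
#' Windowed SSIM with a uniform cubic window, sample-covariance
#' normalization and the standard constants `K1 = 0.01`, `K2 = 0.03`;
#' the mean is taken over fully valid windows. The data range defaults
#' to the range of the reference image `b`.
#'
#' @param a Test image (3D array).
#' @param b Reference image (same shape).
#' @param win Odd window edge length (default 7).
#' @param data_range Intensity range; default `diff(range(b))`.
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
ssim3d <- function(a, b, win = 7L, data_range = NULL) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between images")
  if (any(dim(a) < win)) stop("images smaller than the SSIM window")
  if (is.null(data_range)) data_range <- diff(range(b))
  if (data_range <= 0) stop("degenerate data range")
  NP <- win^3
  cov_norm <- NP / (NP - 1)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  ux <- box_mean3(a, win)
  uy <- box_mean3(b, win)
  uxx <- box_mean3(a * a, win)
  uyy <- box_mean3(b * b, win)
  uxy <- box_mean3(a * b, win)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Classify a phantom image into tissue labels by nearest intensity
#'
#' Assigns each voxel to the tissue (or background, intensity 0) whose
#' mean intensity is closest; the stand-in for a segmentation model on
#' phantom data.
#'
#' @param image 3D intensity array.
#' @param spec The [phantom_spec()] whose tissue means define the classes.
#' @return 3D integer label array in the `phantom_label_ids()` encoding.
#' @export
classify_tissues <- function(image, spec) {
  ids <- phantom_label_ids()
  means <- c(background = 0, spec$tissue_intensity[names(ids)])
  codes <- c(0L, ids[names(ids)])
  v <- as.vector(image)
  d <- abs(outer(v, means, "-"))
  cls <- codes[max.col(-d, ties.method = "first")]
  array(cls, dim = dim(image))
}

# 3^3 neighborhood helpers (edge-replicated shifts)
shift_apply <- function(a, combine, init) {
  d <- dim(a)
  out <- init
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- combine(out, a[xs, ys, zs])
  }
  out
}

dilate3 <- function(mask, iter = 1) {
  for (i in seq_len(iter)) mask <- shift_apply(mask, `|`, mask & FALSE)
  mask
}

# majority vote over the 3^3 neighborhood; absorbs thin misclassified
# shells at blurred tissue boundaries
majority_filter <- function(lab, iter = 1) {
  for (it in seq_len(iter)) {
    vals <- sort(unique(as.vector(lab)))
    best <- array(-1, dim(lab))
    out <- lab
    for (v in vals) {
      cnt <- shift_apply((lab == v) * 1, `+`, array(0, dim(lab)))
      upd <- cnt > best
      best[upd] <- cnt[upd]
      out[upd] <- v
    }
    lab <- out
  }
  lab
}

#' Measure region volumes from an intensity image
#'
#' The segmentation-model stand-in for phantom images: voxels are
#' classified by nearest tissue intensity, a majority filter absorbs the
#' thin misclassified shells that arise at blurred boundaries, and each
#' region's volume is then refined by partial-volume integration — the
#' intensity deficit against white matter, summed over the region core
#' dilated into its white-matter surround. Intensity integrals are
#' conserved by symmetric blur, so the refined volumes are robust to the
#' smoothing of decoded images.
#'
#' @param image 3D intensity array.
#' @param spec The [phantom_spec()] whose tissue means define the classes.
#' @return Named vector of region volumes (% of brain), as
#'   [measure_volumes()].
#' @export
measure_volumes_image <- function(image, spec) {
  ti <- spec$tissue_intensity
  iw <- ti[["white_matter"]]
  ids <- phantom_label_ids()
  lab <- majority_filter(classify_tissues(image, spec))
  v <- c()
  for (r in c("ventricle", "hippocampus", "amygdala", "cortex")) {
    core <- lab == ids[[r]]
    if (!any(core)) { v[r] <- 0; next }
    win <- dilate3(core, 2) & (lab == ids[[r]] | lab == ids[["white_matter"]])
    frac <- pmin((iw - image) / (iw - ti[[r]]), 1)
    v[r] <- sum(frac[win])
  }
  # brain volume: half-level mask plus the dark interior regions it misses
  bright <- sum(image > iw / 2)
  dark_regions <- c("ventricle", "amygdala")[c(ti[["ventricle"]],
                                               ti[["amygdala"]]) < iw / 2]
  brain <- bright + sum(v[dark_regions])
  if (brain <= 0) stop("empty brain mask in intensity image")
  out <- 100 * v / brain
  out["white_matter"] <- max(100 - sum(out), 0)
  out[ALL_REGIONS]
}

#' Per-region volumetric mean absolute error
#'
#' Measures volumes on both inputs (label maps directly; intensity
#' images via [classify_tissues()]) and reports `|v_pred - v_true|` per
#' region in % of brain. Regions absent from the reference are flagged
#' and excluded.
#'
#' @param predicted Predicted image (3D numeric) or label map (integer).
#' @param reference Reference label map.
#' @param spec [phantom_spec()] used for intensity measurement.
#' @param regions Regions to report.
#' @return List with `mae` (named vector) and `excluded` (character).
#' @export
volumetric_mae <- function(predicted, reference, spec,
                           regions = ALL_REGIONS) {
  v_pred <- if (is.integer(predicted) ||
                all(predicted == round(predicted))) {
    measure_volumes(predicted)
  } else {
    measure_volumes_image(predicted, spec)
  }
  v_true <- measure_volumes(reference)
  absent <- regions[v_true[regions] == 0]
  keep <- setdiff(regions, absent)
  list(mae = abs(v_pred[keep] - v_true[keep]), excluded = absent)
}

#' Spearman correlation between voxel uncertainty and squared error
#'
#' Rank correlation restricted to in-mask voxels; background voxels are
#' excluded to avoid artificially inflating the correlation. Constant
#' inputs give a flagged missing value.
#'
#' @param U Voxel uncertainty map.
#' @param err Voxel squared-error map (same shape).
#' @param mask Logical brain mask (same shape), non-empty.
#' @return List with `rho` (possibly `NA`) and `constant` flag.
#' @export
uncertainty_error_correlation <- function(U, err, mask) {
  if (!identical(dim(U), dim(err)) || !identical(dim(U), dim(mask))) {
    stop("shape mismatch among U, err and mask")
  }
  if (!any(mask)) stop("empty mask")
  u <- U[mask]; e <- err[mask]
  if (stats::sd(u) == 0 || stats::sd(e) == 0) {
    return(list(rho = NA_real_, constant = TRUE))
  }
  list(rho = stats::cor(u, e, method = "spearman"), constant = FALSE)
}

#' Pooled trend of global uncertainty with prediction distance
#'
#' For each subject with >= 2 predictions, the prediction distance is
#' `dB_i = B_i - A` and the uncertainty difference `du_i = u_i - u_1`
#' relative to the subject's first prediction. Reports the pooled
#' Spearman correlation of (dB, du) and per-subject least-squares
#' slopes. Single-prediction subjects are skipped and counted.
#'
#' @param predictions Named list: one list of `prediction_result` per
#'   subject (or a data.frame with `subject`, `dB`, `u` columns).
#' @return List with `rho`, `constant` flag, `slopes`, `n_skipped`,
#'   and the pooled `data`.
#' @export
distance_uncertainty_trend <- function(predictions) {
  if (is.data.frame(predictions)) {
    df <- predictions
  } else {
    rows <- list()
    for (sid in names(predictions)) {
      pl <- predictions[[sid]]
      rows[[sid]] <- data.frame(
        subject = sid,
        dB = vapply(pl, function(p) p$B - p$input_age, numeric(1)),
        u = vapply(pl, function(p) p$u, numeric(1))
      )
    }
    df <- do.call(rbind, rows)
  }
  n_skipped <- 0L
  pooled <- list(); slopes <- c()
  for (sid in unique(df$subject)) {
    d <- df[df$subject == sid, , drop = FALSE]
    d <- d[order(d$dB), , drop = FALSE]
    if (nrow(d) < 2) { n_skipped <- n_skipped + 1L; next }
    d$du <- d$u - d$u[1]
    pooled[[sid]] <- d
    slopes[sid] <- stats::coef(stats::lm(du ~ dB, data = d))[["dB"]]
  }
  if (!length(pooled)) stop("no subject has >= 2 predictions")
  all <- do.call(rbind, pooled)
  constant <- stats::sd(all$du) == 0 || stats::sd(all$dB) == 0
  rho <- if (constant) 0 else stats::cor(all$dB, all$du, method = "spearman")
  list(rho = rho, constant = constant, slopes = slopes,
       n_skipped = n_skipped, data = all)
}

#' Select predicted fast progressors and score the overlap
#'
#' Ranks subjects by predicted relative volume reduction
#' `(v_A - v_B) / v_A` in the chosen region, takes the top `S`, and
#' reports the overlap with the top `S` of the observed ranking. Ties
#' are broken by subject id, so the selection is deterministic.
#'
#' @param df data.frame with columns `subject_id`, `v_A`, `v_B_pred`,
#'   `v_B_true`.
#' @param S Number of selected candidates (1..n).
#' @return List with `selected`, `truth`, `overlap` in `[0, 1]`.
#' @export
select_fast_progressors <- function(df, S) {
  n <- nrow(df)
  if (S > n) stop("S = ", S, " exceeds the number of subjects (", n, ")")
  stopifnot(S >= 1)
  red_pred <- (df$v_A - df$v_B_pred) / df$v_A
  red_true <- (df$v_A - df$v_B_true) / df$v_A
  ord_pred <- order(-red_pred, df$subject_id)
  ord_true <- order(-red_true, df$subject_id)
  sel <- df$subject_id[ord_pred[seq_len(S)]]
  tru <- df$subject_id[ord_true[seq_len(S)]]
  list(selected = sel, truth = tru,
       overlap = length(intersect(sel, tru)) / S)
}
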