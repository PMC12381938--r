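# Synthetic longitudinal brain phantoms.
#
# Subjects are rendered as nested ellipsoidal regions inside a brain
# ellipsoid on a regular voxel grid. Region volumes follow logistic
# disease-course trajectories in age, with diagnosis-specific rate
# multipliers, so that simulated cohorts carry a recoverable atrophy
# signal for the downstream models.

PHANTOM_REGIONS <- c("hippocampus", "ventricle", "cortex", "amygdala")
ALL_REGIONS <- c("hippocampus", "ventricle", "cortex", "white_matter", "amygdala")

# Region geometry: centers as fractions of the brain semi-axes, shape
# ratios normalized to unit product so a single radius parameter sets
# the volume. Listed in voxelization precedence order (innermost first).
region_geometry <- function() {
  list(
    ventricle   = list(center = c(0.00,  0.10,  0.05), shape = c(0.9, 1.5, 0.8)),
    hippocampus = list(center = c(-0.48, -0.28, -0.30), shape = c(1.0, 1.9, 0.8)),
    amygdala    = list(center = c(0.48, -0.32, -0.30), shape = c(1.0, 1.0, 1.0)),
    cortex      = list(center = c(0.00,  0.30,  0.42), shape = c(1.3, 1.2, 0.8))
  )
}

# Per-region trajectory parameters: young-age asymptote (base), old-age
# asymptote (limit), logistic steepness per year, and direction.
# Volumes are % of total brain volume.
default_region_params <- function() {
  data.frame(
    region    = c("hippocampus", "ventricle", "cortex", "amygdala"),
    base      = c(0.55, 2.00, 20.0, 0.30),
    limit     = c(0.30, 5.00, 16.0, 0.18),
    steepness = c(0.12, 0.10, 0.06, 0.10),
    direction = c(-1, 1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Phantom rendering specification
#'
#' Describes the voxel grid, tissue intensities and noise level used to
#' render synthetic brain phantoms. Intensities are in `[0, 1]`; noise is
#' i.i.d. Gaussian added within the brain mask only (air carries no
#' tissue signal in this phantom model).
#'
#' @param grid_shape Integer vector of 3 positive voxel counts.
#' @param tissue_intensity Named mean intensity per tissue; must cover
#'   `white_matter`, `cortex`, `ventricle`, `hippocampus`, `amygdala`.
#' @param noise_sd Non-negative intensity noise standard deviation.
#' @param brain_fill Brain semi-axes as a fraction of the half grid.
#' @param seed Integer seed used when no per-call seed is supplied.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 40, 32),
                         tissue_intensity = c(white_matter = 0.75, cortex = 0.55,
                                              ventricle = 0.12, hippocampus = 0.40,
                                              amygdala = 0.28),
                         noise_sd = 0.02,
                         brain_fill = 0.92,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8), noise_sd >= 0,
            brain_fill > 0, brain_fill <= 1)
  need <- setdiff(ALL_REGIONS, names(tissue_intensity))
  if (length(need)) stop("tissue_intensity missing regions: ", paste(need, collapse = ", "))
  structure(list(grid_shape = as.integer(grid_shape),
                 tissue_intensity = tissue_intensity,
                 noise_sd = noise_sd, brain_fill = brain_fill,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Subject trajectory parameters
#'
#' One subject's disease-course parameters: diagnosis-scaled logistic
#' trajectories with midpoint at the subject's onset age. The rate
#' multiplier is the diagnosis multiplier times a log-normal subject
#' random effect.
#'
#' @param subject_id Character id.
#' @param sex `"F"` or `"M"`.
#' @param diagnosis One of `"CN"`, `"MCI"`, `"AD"`.
#' @param onset_age Logistic midpoint age in years.
#' @param base_volumes Named young-age asymptote volumes (% of brain) for
#'   the modelled regions; defaults from [default_region_params()].
#' @param rate_multiplier Unitless trajectory rate scale (diagnosis
#'   multiplier times subject random effect).
#' @param brain_scale Multiplicative total-brain-volume factor (sex effect
#'   times subject size variation).
#' @param region_params Trajectory parameter table (base/limit/steepness/direction).
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id, sex = "F", diagnosis = "CN",
                           onset_age = 75,
                           base_volumes = NULL,
                           rate_multiplier = 1.0,
                           brain_scale = 1.0,
                           region_params = default_region_params()) {
  stopifnot(sex %in% c("F", "M"), diagnosis %in% c("CN", "MCI", "AD"))
  rp <- region_params
  if (!is.null(base_volumes)) {
    unknown <- setdiff(names(base_volumes), rp$region)
    if (length(unknown)) stop("unknown region name(s): ", paste(unknown, collapse = ", "))
    idx <- match(names(base_volumes), rp$region)
    # rescale the old-age limit with the base so relative loss is preserved
    rp$limit[idx] <- rp$limit[idx] * base_volumes / rp$base[idx]
    rp$base[idx] <- base_volumes
  }
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 diagnosis = diagnosis, onset_age = onset_age,
                 rate_multiplier = rate_multiplier,
                 brain_scale = brain_scale,
                 region_params = rp),
            class = "subject_params")
}

#' Default diagnosis rate multipliers
#' @return Named numeric vector (CN, MCI, AD).
#' @export
diagnosis_multipliers <- function() c(CN = 1.0, MCI = 1.6, AD = 2.5)

#' Evaluate a subject's regional volume trajectory
#'
#' Logistic disease course in age: atrophying regions decrease from their
#' base towards a floor, expanding regions (ventricles) increase towards a
#' ceiling, with midpoint at the subject's onset age and steepness scaled
#' by the subject's rate multiplier.
#'
#' @param params A [subject_params()] object.
#' @param age Age in years (vectorized).
#' @param regions Which regions to evaluate (default: all modelled).
#' @return Matrix `length(age) x length(regions)` of volumes in % of brain.
#' @export
volume_trajectory <- function(params, age, regions = PHANTOM_REGIONS) {
  stopifnot(inherits(params, "subject_params"))
  rp <- params$region_params
  unknown <- setdiff(regions, rp$region)
  if (length(unknown)) stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  out <- matrix(NA_real_, length(age), length(regions),
                dimnames = list(NULL, regions))
  for (r in regions) {
    i <- match(r, rp$region)
    u <- rp$steepness[i] * params$rate_multiplier * (age - params$onset_age)
    # direction -1: decreasing from base to limit; +1: increasing base -> limit
    if (rp$direction[i] < 0) {
      out[, r] <- rp$limit[i] + (rp$base[i] - rp$limit[i]) * stats::plogis(-u)
    } else {
      out[, r] <- rp$base[i] + (rp$limit[i] - rp$base[i]) * stats::plogis(u)
    }
  }
  out
}

# voxel-center coordinate arrays in brain-semi-axis units
phantom_coords <- function(grid_shape, brain_fill, brain_scale) {
  n <- grid_shape
  semi <- brain_fill * (n - 1) / 2 * brain_scale^(1 / 3)
  ctr <- (n + 1) / 2
  xs <- (seq_len(n[1]) - ctr[1]) / semi[1]
  ys <- (seq_len(n[2]) - ctr[2]) / semi[2]
  zs <- (seq_len(n[3]) - ctr[3]) / semi[3]
  X <- array(rep(xs, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(zs, each = n[1] * n[2]), dim = n)
  list(X = X, Y = Y, Z = Z)
}

# Label encoding used throughout: 0 background, 1 white matter (brain
# remainder), then one id per modelled region.
phantom_label_ids <- function() {
  c(white_matter = 1L, cortex = 2L, ventricle = 3L, hippocampus = 4L, amygdala = 5L)
}

#' Render one phantom image and label map
#'
#' Voxelizes nested ellipsoidal regions so that the measured label volumes
#' match the requested percentages up to voxel-count ties, then fills
#' tissues with their mean intensities plus seeded Gaussian noise inside
#' the brain mask. Deterministic given all arguments.
#'
#' @param volumes Named vector of requested region volumes (% of brain)
#'   for the modelled regions (`hippocampus`, `ventricle`, `cortex`,
#'   `amygdala`); white matter is the brain remainder.
#' @param params A [subject_params()] object (brain scale, geometry).
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the intensity noise.
#' @param center_jitter Optional named list/matrix of per-region center
#'   offsets in voxels (visit-to-visit positioning variability).
#' @param shape_scale Optional named list of per-region 3-vectors
#'   multiplying the region shape ratios (anisotropy drift); volumes are
#'   unaffected because shapes are renormalized to unit product.
#' @return List with `image` (3D array in `[0,1]` range plus noise) and
#'   `labels` (3D integer array, see `phantom_label_ids()`).
#' @export
render_phantom <- function(volumes, params, spec, seed = spec$seed,
                           center_jitter = NULL, shape_scale = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(params, "subject_params"))
  unknown <- setdiff(names(volumes), PHANTOM_REGIONS)
  if (length(unknown)) stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  n <- spec$grid_shape
  co <- phantom_coords(n, spec$brain_fill, params$brain_scale)
  d2_brain <- co$X^2 + co$Y^2 + co$Z^2
  brain <- d2_brain <= 1
  brain_count <- sum(brain)
  if (brain_count == 0) stop("empty brain mask: grid too small for brain_fill")

  ids <- phantom_label_ids()
  labels <- array(0L, dim = n)
  labels[brain] <- ids[["white_matter"]]

  geom <- region_geometry()
  semi_vox <- spec$brain_fill * (n - 1) / 2 * params$brain_scale^(1 / 3)
  available <- brain
  for (r in names(geom)) {
    if (!r %in% names(volumes)) next
    pct <- volumes[[r]]
    if (is.na(pct)) next
    target <- round(pct / 100 * brain_count)
    if (target == 0) next
    g <- geom[[r]]
    ctr <- g$center
    if (!is.null(center_jitter) && !is.null(center_jitter[[r]])) {
      ctr <- ctr + center_jitter[[r]] / semi_vox
    }
    sh <- g$shape
    if (!is.null(shape_scale) && !is.null(shape_scale[[r]])) {
      sh <- sh * shape_scale[[r]]
    }
    sh <- sh / prod(sh)^(1 / 3)
    d2 <- ((co$X - ctr[1]) / sh[1])^2 + ((co$Y - ctr[2]) / sh[2])^2 +
      ((co$Z - ctr[3]) / sh[3])^2
    d2a <- d2[available]
    if (target > length(d2a)) {
      stop("requested volume not geometrically feasible for region: ", r)
    }
    thr <- sort(d2a, partial = target)[target]
    sel <- available & d2 <= thr
    labels[sel] <- ids[[r]]
    available <- available & !sel
  }

  img <- array(0, dim = n)
  for (r in names(ids)) img[labels == ids[[r]]] <- spec$tissue_intensity[[r]]
  if (spec$noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(brain_count, 0, spec$noise_sd))
    img[brain] <- img[brain] + noise
  }
  list(image = img, labels = labels)
}

#' Measure region volumes from a label map
#'
#' Volumes are per-region voxel counts divided by the brain-mask voxel
#' count (all non-zero labels), times 100.
#'
#' @param labels 3D integer label array (see `phantom_label_ids()`).
#' @return Named vector of volumes (% of brain) over all regions.
#' @export
measure_volumes <- function(labels) {
  ids <- phantom_label_ids()
  brain_count <- sum(labels > 0)
  if (brain_count == 0) stop("empty brain mask: no non-zero labels")
  out <- vapply(names(ids), function(r) {
    100 * sum(labels == ids[[r]]) / brain_count
  }, numeric(1))
  out[ALL_REGIONS]
}

#' Simulate a longitudinal phantom cohort
#'
#' Draws subjects with diagnosis-dependent disease-course parameters,
#' renders every visit, and returns the covariate table together with the
#' in-memory images and label maps. Volumes recorded in the table are
#' measured from the emitted label maps. Optionally writes NIfTI images,
#' label maps and the covariate CSV to `out_dir`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param visits_per_subject Visits per subject (>= 2).
#' @param age_range Baseline age range in years.
#' @param diagnosis_mix Named probabilities over CN/MCI/AD.
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; fixed seeds reproduce the cohort exactly.
#' @param out_dir Optional output directory for NIfTI/CSV artifacts.
#' @param visit_interval Range (years) of between-visit gaps, or a single
#'   number for fixed spacing.
#' @param rate_sd Log-normal sd of the subject rate random effect.
#' @param base_sd Log-normal sd of per-region base-volume variation.
#' @param size_sd Log-normal sd of total brain size variation.
#' @param center_jitter_sd Per-visit region-center jitter sd in voxels;
#'   the default emulates the subvoxel residuals of affinely registered
#'   cohorts.
#' @param shape_drift_sd Per-axis sd of each subject-region's
#'   log-anisotropy drift rate (per year). Region shapes evolve as
#'   `exp(g * (age - baseline age))` with `g ~ N(0, shape_drift_sd^2)`,
#'   emulating progressive anatomical change that the volume covariates
#'   do not summarize; prediction uncertainty therefore genuinely grows
#'   with the forecasting horizon.
#' @param dx_multipliers Diagnosis rate multipliers.
#' @param onset_means Named mean onset age per diagnosis.
#' @param trajectory `"logistic"` (default) or `"linear"`; linear applies
#'   a constant per-year change of size steepness x multiplier x
#'   (base - limit) / 4 (the logistic mid-course slope).
#' @return An object of class `phantom_cohort`: list with `table`
#'   (data.frame), `images`, `labels` (lists of 3D arrays), `subjects`
#'   (list of [subject_params()]).
#' @export
simulate_cohort <- function(n_subjects, visits_per_subject = 3,
                            age_range = c(60, 85),
                            diagnosis_mix = c(CN = 0.4, MCI = 0.3, AD = 0.3),
                            spec = phantom_spec(), seed = 1L,
                            out_dir = NULL,
                            visit_interval = c(1.5, 3),
                            rate_sd = 0.2, base_sd = 0.05, size_sd = 0.03,
                            center_jitter_sd = 0.1,
                            shape_drift_sd = 0.012,
                            dx_multipliers = diagnosis_multipliers(),
                            onset_means = c(CN = 80, MCI = 75, AD = 71),
                            trajectory = c("logistic", "linear")) {
  stopifnot(n_subjects >= 1, visits_per_subject >= 2)
  trajectory <- match.arg(trajectory)
  if (length(visit_interval) == 1) visit_interval <- rep(visit_interval, 2)

  draw <- with_seed(derive_seed(seed, "cohort"), {
    lapply(seq_len(n_subjects), function(i) {
      dx <- sample(names(diagnosis_mix), 1, prob = diagnosis_mix)
      sex <- sample(c("F", "M"), 1)
      rp <- default_region_params()
      base <- stats::setNames(rp$base * exp(stats::rnorm(nrow(rp), 0, base_sd)), rp$region)
      p <- subject_params(
        subject_id = sprintf("S%04d", i), sex = sex, diagnosis = dx,
        onset_age = stats::rnorm(1, onset_means[[dx]], 4),
        base_volumes = base,
        rate_multiplier = dx_multipliers[[dx]] * exp(stats::rnorm(1, 0, rate_sd)),
        brain_scale = (if (sex == "M") 1.08 else 1.0) * exp(stats::rnorm(1, 0, size_sd))
      )
      a0 <- stats::runif(1, age_range[1], age_range[2])
      gaps <- stats::runif(visits_per_subject - 1, visit_interval[1], visit_interval[2])
      ages <- a0 + c(0, cumsum(gaps))
      jit <- lapply(seq_len(visits_per_subject), function(v) {
        lapply(region_geometry(), function(g) stats::rnorm(3, 0, center_jitter_sd))
      })
      drift <- lapply(region_geometry(), function(g) {
        stats::rnorm(3, 0, shape_drift_sd)
      })
      list(params = p, ages = ages, jitter = jit, drift = drift)
    })
  })

  rows <- list(); images <- list(); labels <- list()
  k <- 0L
  for (s in draw) {
    p <- s$params
    for (v in seq_along(s$ages)) {
      k <- k + 1L
      age <- s$ages[v]
      vols <- if (trajectory == "logistic") {
        volume_trajectory(p, age)[1, ]
      } else {
        linear_trajectory(p, age)
      }
      dt <- age - s$ages[1]
      rnd <- render_phantom(vols, p, spec,
                            seed = derive_seed(seed, paste0(p$subject_id, "_v", v)),
                            center_jitter = s$jitter[[v]],
                            shape_scale = lapply(s$drift, function(g) exp(g * dt)))
      meas <- measure_volumes(rnd$labels)
      rows[[k]] <- data.frame(
        subject_id = p$subject_id, age = age, sex = p$sex, diagnosis = p$diagnosis,
        image = NA_character_, labels = NA_character_,
        vol_hippocampus = meas[["hippocampus"]],
        vol_ventricle = meas[["ventricle"]],
        vol_cortex = meas[["cortex"]],
        vol_white_matter = meas[["white_matter"]],
        vol_amygdala = meas[["amygdala"]],
        stringsAsFactors = FALSE
      )
      images[[k]] <- rnd$image
      labels[[k]] <- rnd$labels
    }
  }
  tab <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
    for (i in seq_len(nrow(tab))) {
      stem <- sprintf("%s_%05.1fy", tab$subject_id[i], tab$age[i])
      imgf <- file.path(out_dir, paste0(stem, ".nii.gz"))
      labf <- file.path(out_dir, paste0(stem, "_labels.nii.gz"))
      save_image(images[[i]], imgf)
      save_image(labels[[i]], labf)
      tab$image[i] <- imgf
      tab$labels[i] <- labf
    }
    utils::write.csv(tab, file.path(out_dir, "covariates.csv"), row.names = FALSE)
  }

  structure(list(table = tab, images = images, labels = labels,
                 subjects = lapply(draw, `[[`, "params"), spec = spec,
                 seed = as.integer(seed)),
            class = "phantom_cohort")
}

# constant per-year change at the logistic mid-course slope; kept
# unclamped (up to a positivity guard) so fitted rates are exactly the
# generator rates
linear_trajectory <- function(params, age) {
  rp <- params$region_params
  vols <- numeric(nrow(rp))
  names(vols) <- rp$region
  for (i in seq_len(nrow(rp))) {
    slope <- rp$direction[i] * abs(rp$base[i] - rp$limit[i]) *
      rp$steepness[i] * params$rate_multiplier / 4
    mid <- (rp$base[i] + rp$limit[i]) / 2
    vols[i] <- max(mid + slope * (age - params$onset_age), 0.02 * mid)
  }
  vols
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tab <- x$table
  cat("phantom cohort:", length(unique(tab$subject_id)), "subjects,",
      nrow(tab), "visits, grid", paste(x$spec$grid_shape, collapse = "x"), "\n")
  cat("diagnoses:", paste(names(table(tab$diagnosis[!duplicated(tab$subject_id)])),
                          table(tab$diagnosis[!duplicated(tab$subject_id)]),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}
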