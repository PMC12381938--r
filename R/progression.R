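# Auxiliary disease-course forecasters for progression-related volumes.
#
# Two model families, chosen by the amount of data available per subject:
#  * linear change model for single-visit inputs: the per-year volume
#    change of each region is a linear function of the visit covariates,
#    so the forecast is exact at zero horizon;
#  * simplified logistic disease-course model for visit histories: each
#    region follows a population logistic curve in age, and a subject is
#    mapped onto it by a time shift tau and log-acceleration xi
#    (u = exp(xi) * (age - t0 - tau)), estimated by penalized nonlinear
#    least squares.
# Any forecaster implementing predict_volumes() can be plugged into the
# inference pipeline.

AUX_REGIONS <- c("hippocampus", "ventricle", "cortex", "white_matter", "amygdala")

#' Fit the linear auxiliary change model
#'
#' Regresses per-year volume change over all ordered same-subject visit
#' pairs on the starting-visit covariates (sex, diagnosis, centered age
#' and centered region volume), one least-squares fit per region.
#'
#' @param table Cohort covariate data.frame (`subject_id`, `age`, `sex`,
#'   `diagnosis`, `vol_*` columns).
#' @param regions Regions to model (default: all five tracked regions).
#' @return Object of class `linear_aux` with per-region coefficients and
#'   fit diagnostics.
#' @export
fit_linear_aux <- function(table, regions = AUX_REGIONS) {
  vols <- cohort_volume_matrix(table)
  ia <- integer(0); ib <- integer(0)
  for (sid in unique(table$subject_id)) {
    idx <- which(table$subject_id == sid)
    idx <- idx[order(table$age[idx])]
    k <- length(idx)
    if (k < 2) next
    pr <- utils::combn(k, 2)
    ia <- c(ia, idx[pr[1, ]]); ib <- c(ib, idx[pr[2, ]])
  }
  if (!length(ia)) stop("no visit pairs available to fit the change model")
  dt <- table$age[ib] - table$age[ia]
  age_c <- mean(table$age[ia])
  fits <- list(); vol_c <- numeric(0)
  for (r in regions) {
    v_c <- mean(vols[ia, r])
    vol_c[r] <- v_c
    df <- data.frame(
      rate = (vols[ib, r] - vols[ia, r]) / dt,
      sexM = as.numeric(table$sex[ia] == "M"),
      dxMCI = as.numeric(table$diagnosis[ia] == "MCI"),
      dxAD = as.numeric(table$diagnosis[ia] == "AD"),
      age = table$age[ia] - age_c,
      vol = vols[ia, r] - v_c
    )
    fit <- stats::lm(rate ~ sexM + dxMCI + dxAD + age + vol, data = df)
    al <- stats::alias(fit)$Complete
    if (!is.null(al) && nrow(al)) {
      stop("rank-deficient design; collinear feature(s): ",
           paste(rownames(al), collapse = ", "))
    }
    fits[[r]] <- list(coef = stats::coef(fit), sigma = summary(fit)$sigma,
                      r2 = summary(fit)$r.squared)
  }
  structure(list(fits = fits, regions = regions, age_center = age_c,
                 vol_center = vol_c, n_pairs = length(ia)),
            class = "linear_aux")
}

#' Forecast progression-related volumes
#'
#' Generic over auxiliary model families. Forecasting is forward-only:
#' a target age below the input (or last observed) age is an error.
#'
#' @param model A fitted auxiliary model.
#' @param input For `linear_aux`: a one-row data.frame with `age`, `sex`,
#'   `diagnosis` and `vol_*` columns. For `course_fit`: ignored (the
#'   subject calibration is in the model).
#' @param B Target age in years.
#' @param ... Unused.
#' @return Named vector of forecast volumes (% of brain).
#' @export
predict_volumes <- function(model, input, B, ...) UseMethod("predict_volumes")

#' @export
predict_volumes.linear_aux <- function(model, input, B, ...) {
  stopifnot(nrow(input) == 1)
  if (B < input$age) {
    stop("target age B = ", B, " is below the input age A = ", input$age,
         "; the model forecasts forward only")
  }
  vols <- cohort_volume_matrix(input)[1, ]
  out <- vols[model$regions]
  for (r in model$regions) {
    cf <- model$fits[[r]]$coef
    x <- c(1,
           as.numeric(input$sex == "M"),
           as.numeric(input$diagnosis == "MCI"),
           as.numeric(input$diagnosis == "AD"),
           input$age - model$age_center,
           vols[r] - model$vol_center[r])
    out[r] <- vols[r] + (B - input$age) * sum(cf * x)
  }
  out
}

# --- logistic disease-course model -----------------------------------------

#' Population logistic disease-course model
#'
#' Each region follows
#' `v(age) = floor + (ceiling - floor) * plogis(dir * k * u)` with the
#' subject-reparameterized age `u = exp(xi) * (age - t0 - tau)`;
#' `dir = +1` for expanding regions, `-1` for atrophying ones.
#'
#' @param params data.frame with columns `region`, `floor`, `ceiling`,
#'   `steepness`, `t0`, `direction`.
#' @param noise_sd Observation noise sd (% of brain).
#' @return Object of class `course_model`.
#' @export
logistic_course_model <- function(params, noise_sd = 0.05) {
  need <- c("region", "floor", "ceiling", "steepness", "t0", "direction")
  stopifnot(all(need %in% names(params)), all(params$floor < params$ceiling),
            all(params$steepness > 0))
  structure(list(params = params, noise_sd = noise_sd), class = "course_model")
}

#' Default population course prior matched to typical cohort scales
#' @return A [logistic_course_model()].
#' @export
default_course_prior <- function() {
  rp <- default_region_params()
  logistic_course_model(data.frame(
    region = rp$region,
    floor = pmin(rp$base, rp$limit),
    ceiling = pmax(rp$base, rp$limit),
    steepness = rp$steepness,
    t0 = 75,
    direction = rp$direction,
    stringsAsFactors = FALSE
  ))
}

course_curve <- function(prior, region, age, tau = 0, xi = 0) {
  p <- prior$params[prior$params$region == region, ]
  if (!nrow(p)) stop("unknown region in course model: ", region)
  u <- exp(xi) * (age - p$t0 - tau)
  p$floor + (p$ceiling - p$floor) * stats::plogis(p$direction * p$steepness * u)
}

#' Calibrate the course model to a subject's visit history
#'
#' Estimates the subject time shift tau and log-acceleration xi by
#' penalized nonlinear least squares around the population curve, with
#' residuals scaled by each region's dynamic range. Multi-start
#' optimization; if no start converges, the population prior (tau = 0,
#' xi = 0) is returned with `converged = FALSE`.
#'
#' @param history data.frame of the subject's visits (`age`, `vol_*`
#'   columns), >= 2 rows.
#' @param prior A [logistic_course_model()].
#' @param regions Regions entering the fit.
#' @param penalty Ridge penalties `c(tau, xi)` on (tau/10)^2 and xi^2.
#' @return Object of class `course_fit` with `tau`, `xi`, `converged`.
#' @export
fit_course_model <- function(history, prior,
                             regions = intersect(prior$params$region, AUX_REGIONS),
                             penalty = c(tau = 1e-4, xi = 1e-3)) {
  stopifnot(inherits(prior, "course_model"), nrow(history) >= 2)
  vols <- cohort_volume_matrix(history)
  scales <- vapply(regions, function(r) {
    p <- prior$params[prior$params$region == r, ]
    p$ceiling - p$floor
  }, numeric(1))
  obj <- function(par) {
    tau <- par[1]; xi <- par[2]
    sse <- 0
    for (i in seq_along(regions)) {
      r <- regions[i]
      pred <- course_curve(prior, r, history$age, tau, xi)
      sse <- sse + sum(((vols[, r] - pred) / scales[i])^2)
    }
    sse + penalty[["tau"]] * (tau / 10)^2 + penalty[["xi"]] * xi^2
  }
  starts <- expand.grid(tau = c(-10, 0, 10), xi = c(-0.5, 0, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = c(-40, -5), upper = c(40, 3)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(structure(list(prior = prior, tau = 0, xi = 0, regions = regions,
                          converged = FALSE), class = "course_fit"))
  }
  structure(list(prior = prior, tau = best$par[1], xi = best$par[2],
                 regions = regions, converged = best$convergence == 0,
                 objective = best$value,
                 last_age = max(history$age)),
            class = "course_fit")
}

#' @export
predict_volumes.course_fit <- function(model, input = NULL, B, ...) {
  last_age <- model$last_age %||% -Inf
  if (B < last_age) {
    stop("target age B = ", B, " is below the last observed age ", last_age,
         "; the model forecasts forward only")
  }
  out <- vapply(model$regions, function(r) {
    course_curve(model$prior, r, B, model$tau, model$xi)
  }, numeric(1))
  names(out) <- model$regions
  out
}

#' Fit population course parameters by alternating optimization
#'
#' Alternates between (a) calibrating every subject's (tau, xi) given the
#' population parameters and (b) refitting each region's floor, ceiling,
#' steepness and t0 given the subject effects, until the objective
#' improves by less than `tol` or `max_outer` iterations.
#'
#' @param table Cohort covariate data.frame.
#' @param init Initial [logistic_course_model()] (default: data-driven).
#' @param regions Regions to model.
#' @param max_outer Maximum outer iterations.
#' @param tol Relative objective tolerance.
#' @return A [logistic_course_model()] with fitted population parameters.
#' @export
fit_course_population <- function(table, init = NULL,
                                  regions = intersect(AUX_REGIONS,
                                                      default_region_params()$region),
                                  max_outer = 20, tol = 1e-6) {
  vols <- cohort_volume_matrix(table)
  if (is.null(init)) {
    rp <- default_region_params()
    init <- logistic_course_model(data.frame(
      region = regions,
      floor = vapply(regions, function(r) min(vols[, r]) * 0.9, numeric(1)),
      ceiling = vapply(regions, function(r) max(vols[, r]) * 1.1, numeric(1)),
      steepness = rp$steepness[match(regions, rp$region)],
      t0 = stats::median(table$age),
      direction = rp$direction[match(regions, rp$region)],
      stringsAsFactors = FALSE
    ))
  }
  prior <- init
  subjects <- unique(table$subject_id)
  total_obj <- function(prior, effects) {
    s <- 0
    for (j in seq_along(subjects)) {
      h <- table[table$subject_id == subjects[j], , drop = FALSE]
      v <- cohort_volume_matrix(h)
      for (r in regions) {
        p <- prior$params[prior$params$region == r, ]
        pred <- course_curve(prior, r, h$age, effects[j, 1], effects[j, 2])
        s <- s + sum(((v[, r] - pred) / (p$ceiling - p$floor))^2)
      }
    }
    s
  }
  prev <- Inf
  effects <- matrix(0, length(subjects), 2)
  for (it in seq_len(max_outer)) {
    for (j in seq_along(subjects)) {
      h <- table[table$subject_id == subjects[j], , drop = FALSE]
      f <- fit_course_model(h, prior, regions)
      effects[j, ] <- c(f$tau, f$xi)
    }
    for (r in regions) {
      i <- which(prior$params$region == r)
      p0 <- prior$params[i, ]
      obj_r <- function(par) {
        pr <- prior
        pr$params$floor[i] <- par[1]
        pr$params$ceiling[i] <- par[1] + exp(par[2])
        pr$params$steepness[i] <- exp(par[3])
        pr$params$t0[i] <- par[4]
        s <- 0
        for (j in seq_along(subjects)) {
          h <- table[table$subject_id == subjects[j], , drop = FALSE]
          v <- cohort_volume_matrix(h)
          pred <- course_curve(pr, r, h$age, effects[j, 1], effects[j, 2])
          s <- s + sum(((v[, r] - pred) / exp(par[2]))^2)
        }
        s
      }
      res <- stats::optim(c(p0$floor, log(p0$ceiling - p0$floor),
                            log(p0$steepness), p0$t0), obj_r,
                          method = "Nelder-Mead",
                          control = list(maxit = 200))
      prior$params$floor[i] <- res$par[1]
      prior$params$ceiling[i] <- res$par[1] + exp(res$par[2])
      prior$params$steepness[i] <- exp(res$par[3])
      prior$params$t0[i] <- res$par[4]
    }
    cur <- total_obj(prior, effects)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(1, prev)) break
    prev <- cur
  }
  prior
}
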