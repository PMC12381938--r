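# Auxiliary volume forecasters: linear change model and logistic
# disease-course model.

test_that("the linear change model is exact at zero horizon and errors backwards", {
  co <- small_cohort()
  aux <- fit_linear_aux(co$table)
  row <- co$table[1, , drop = FALSE]
  v <- predict_volumes(aux, row, row$age)
  expect_equal(v[["hippocampus"]], row$vol_hippocampus)
  expect_equal(v[["ventricle"]], row$vol_ventricle)
  expect_error(predict_volumes(aux, row, row$age - 1), "forecasts forward")
})

test_that("hand-built linear coefficients produce the expected arithmetic", {
  aux <- structure(list(
    fits = list(hippocampus = list(coef = c(`(Intercept)` = -0.002, sexM = 0,
                                            dxMCI = 0, dxAD = 0, age = 0,
                                            vol = 0))),
    regions = "hippocampus", age_center = 70,
    vol_center = c(hippocampus = 0.5), n_pairs = 1
  ), class = "linear_aux")
  row <- data.frame(subject_id = "X", age = 70, sex = "F", diagnosis = "CN",
                    vol_hippocampus = 0.5, vol_ventricle = 2, vol_cortex = 20,
                    vol_white_matter = 70, vol_amygdala = 0.3)
  v <- predict_volumes(aux, row, 75)
  expect_equal(v[["hippocampus"]], 0.5 - 0.010)
})

test_that("per-diagnosis atrophy rates are recovered from a constant-rate cohort", {
  co <- linear_cohort_200()
  aux <- fit_linear_aux(co$table)
  tab <- co$table
  base_rows <- tab[!duplicated(tab$subject_id), ]
  for (dx in c("CN", "MCI", "AD")) {
    rows <- base_rows[base_rows$diagnosis == dx, ]
    sub <- co$subjects[match(rows$subject_id,
                             vapply(co$subjects, `[[`, "", "subject_id"))]
    true_rate <- mean(vapply(sub, function(p) {
      rp <- p$region_params
      j <- match("hippocampus", rp$region)
      rp$direction[j] * abs(rp$base[j] - rp$limit[j]) * rp$steepness[j] *
        p$rate_multiplier / 4
    }, numeric(1)))
    pred_rate <- mean(vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, , drop = FALSE]
      (predict_volumes(aux, r, r$age + 1)[["hippocampus"]] - r$vol_hippocampus)
    }, numeric(1)))
    expect_lt(abs(pred_rate - true_rate) / abs(true_rate), 0.10)
  }
})

test_that("a null-rate cohort yields near-zero change coefficients", {
  co <- memo("null_cohort", function() {
    simulate_cohort(40, 3, spec = phantom_spec(), seed = 77,
                    dx_multipliers = c(CN = 0, MCI = 0, AD = 0),
                    trajectory = "logistic")
  })
  aux <- fit_linear_aux(co$table)
  # all predicted per-year rates are tiny relative to typical volumes
  row <- co$table[1, , drop = FALSE]
  v1 <- predict_volumes(aux, row, row$age + 1)
  expect_lt(abs(v1[["ventricle"]] - row$vol_ventricle), 0.02)
  expect_lt(abs(v1[["hippocampus"]] - row$vol_hippocampus), 0.01)
})

course_history <- function(prior, tau, xi, ages) {
  vols <- vapply(intersect(prior$params$region, latentcourse:::AUX_REGIONS),
                 function(r) latentcourse:::course_curve(prior, r, ages, tau, xi),
                 numeric(length(ages)))
  df <- data.frame(subject_id = "S", age = ages, sex = "F", diagnosis = "AD")
  for (r in latentcourse:::ALL_REGIONS) {
    df[[paste0("vol_", r)]] <- if (r %in% colnames(vols)) vols[, r] else 50
  }
  df
}

test_that("subject time shift and acceleration are recovered from noiseless histories", {
  prior <- default_course_prior()
  for (case in list(c(tau = 6, xi = 0.4), c(tau = -8, xi = -0.3))) {
    h <- course_history(prior, case[["tau"]], case[["xi"]],
                        ages = c(68, 71, 74, 77))
    fit <- fit_course_model(h, prior)
    expect_true(fit$converged)
    expect_lt(abs(fit$tau - case[["tau"]]) / abs(case[["tau"]]), 0.15)
    expect_lt(abs(fit$xi - case[["xi"]]) / abs(case[["xi"]]), 0.15)
  }
})

test_that("shifting all visit ages shifts the estimated time shift equally", {
  prior <- default_course_prior()
  h <- course_history(prior, tau = 3, xi = 0.2, ages = c(69, 72, 75, 78))
  f0 <- fit_course_model(h, prior)
  delta <- 4
  h2 <- h; h2$age <- h$age + delta
  f2 <- fit_course_model(h2, prior)
  expect_lt(abs((f2$tau - f0$tau) - delta), 0.2)
})

test_that("flat histories drive the acceleration down and predictions constant", {
  prior <- default_course_prior()
  h <- course_history(prior, 0, 0, ages = c(70, 73, 76, 79))
  mid <- vapply(latentcourse:::ALL_REGIONS, function(r) {
    p <- prior$params[prior$params$region == r, ]
    if (nrow(p)) (p$floor + p$ceiling) / 2 else 50
  }, numeric(1))
  for (r in names(mid)) h[[paste0("vol_", r)]] <- mid[[r]]
  fit <- fit_course_model(h, prior)
  expect_lt(fit$xi, -1.5) # strongly decelerated, i.e. a flat curve
  preds <- vapply(c(80, 85, 90), function(B) {
    predict_volumes(fit, NULL, B)[["hippocampus"]]
  }, numeric(1))
  # over a decade the forecast moves by a tiny fraction of the region's
  # dynamic range (0.25% of brain)
  expect_lt(diff(range(preds)), 0.05)
})

test_that("logistic forecasts stay inside the asymptotes and reach the floor", {
  prior <- default_course_prior()
  h <- course_history(prior, 0, 0.3, ages = c(70, 73, 76))
  fit <- fit_course_model(h, prior)
  p <- prior$params[prior$params$region == "hippocampus", ]
  Bs <- c(77, 80, 85, 95, 120)
  preds <- vapply(Bs, function(B) predict_volumes(fit, NULL, B)[["hippocampus"]],
                  numeric(1))
  expect_true(all(preds > p$floor & preds < p$ceiling))
  expect_true(all(diff(preds) < 0)) # monotone forecasts for atrophy
  expect_lt(predict_volumes(fit, NULL, 300)[["hippocampus"]] - p$floor, 1e-6)
  expect_error(predict_volumes(fit, NULL, 60), "forecasts forward")
})

test_that("held-out later visits of a simulated subject are forecast accurately", {
  prior <- default_course_prior()
  ages <- c(66, 69, 72, 75, 80, 84)
  h <- course_history(prior, tau = 2, xi = 0.25, ages = ages)
  fit <- fit_course_model(h[1:4, ], prior)
  for (i in 5:6) {
    truth <- h$vol_hippocampus[i]
    pred <- predict_volumes(fit, NULL, ages[i])[["hippocampus"]]
    expect_lt(abs(pred - truth) / truth, 0.10)
  }
})

test_that("population course fitting improves on a perturbed initialization", {
  prior <- default_course_prior()
  set.seed(55)
  rows <- lapply(1:12, function(i) {
    tau <- rnorm(1, 0, 5); xi <- rnorm(1, 0, 0.2)
    h <- course_history(prior, tau, xi, ages = seq(68, 77, by = 3))
    h$subject_id <- sprintf("P%02d", i)
    h
  })
  tab <- do.call(rbind, rows)
  init <- prior
  init$params$t0 <- init$params$t0 + 6
  fitted <- fit_course_population(tab, init = init, max_outer = 3)
  # the fitted population midpoint age moves back towards the truth
  expect_lt(mean(abs(fitted$params$t0 - 75)), 6)
})
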