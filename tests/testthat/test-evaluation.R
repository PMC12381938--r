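# Evaluation metrics: image similarity, volumes, correlations, selection.

test_that("MSE has its closed-form values", {
  a <- array(runif(4^3), c(4, 4, 4))
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a + 0.3, a), 0.09)
  expect_error(mse(a, array(0, c(4, 4, 5))), "shape mismatch")
})

# direct windowed SSIM by explicit loops; independent of the cumulative
# box-filter implementation in the package
ssim_brute <- function(a, b, win = 7, data_range = diff(range(b))) {
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  d <- dim(a); pad <- (win - 1) / 2
  NP <- win^3; cn <- NP / (NP - 1)
  vals <- c()
  for (i in (1 + pad):(d[1] - pad)) for (j in (1 + pad):(d[2] - pad))
    for (k in (1 + pad):(d[3] - pad)) {
      wa <- a[(i - pad):(i + pad), (j - pad):(j + pad), (k - pad):(k + pad)]
      wb <- b[(i - pad):(i + pad), (j - pad):(j + pad), (k - pad):(k + pad)]
      ux <- mean(wa); uy <- mean(wb)
      vx <- cn * (mean(wa^2) - ux^2); vy <- cn * (mean(wb^2) - uy^2)
      vxy <- cn * (mean(wa * wb) - ux * uy)
      vals <- c(vals, ((2 * ux * uy + C1) * (2 * vxy + C2)) /
                  ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

test_that("ssim3d equals the direct windowed definition and its limits", {
  set.seed(8)
  a <- array(runif(11^3), c(11, 11, 11))
  expect_equal(ssim3d(a, a), 1)
  b <- a + array(rnorm(11^3, 0, 0.1), c(11, 11, 11))
  expect_equal(ssim3d(b, a), ssim_brute(b, a), tolerance = 1e-12)
  expect_lt(ssim3d(a + 0.2, a), 1)
  expect_error(ssim3d(a, array(0, c(11, 11, 12))), "shape mismatch")
})

test_that("ssim3d agrees with the scikit-image reference implementation", {
  set.seed(99)
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  results <- c()
  expected <- c()
  for (i in 1:4) {
    a <- array(runif(32^3), c(32, 32, 32))
    b <- pmin(pmax(a + array(rnorm(32^3, 0, 0.08), c(32, 32, 32)), 0), 1)
    writeBin(c(as.vector(a), as.vector(b)), tmp, size = 8)
    py <- sprintf(paste0(
      "import numpy as np; from skimage.metrics import structural_similarity as s;",
      "d=np.fromfile('%s'); a=d[:32**3].reshape((32,32,32),order='F');",
      "b=d[32**3:].reshape((32,32,32),order='F');",
      "print(float(s(b,a,win_size=7,data_range=float(a.max()-a.min()))))"), tmp)
    ref <- as.numeric(system2("python", c("-c", shQuote(py)), stdout = TRUE))
    results <- c(results, ssim3d(b, a))
    expected <- c(expected, ref)
  }
  expect_equal(results, expected, tolerance = 1e-6)
})

test_that("volume measurement recovers label-map volumes from sharp and noisy images", {
  sp <- phantom_spec(c(32, 40, 32))
  p <- subject_params("S1", diagnosis = "MCI", onset_age = 70)
  v <- volume_trajectory(p, 74)[1, ]
  r <- render_phantom(v, p, sp, seed = 4)
  truth <- measure_volumes(r$labels)
  est <- measure_volumes_image(r$image, sp)
  expect_lt(abs(est[["ventricle"]] - truth[["ventricle"]]), 0.25)
  expect_lt(abs(est[["hippocampus"]] - truth[["hippocampus"]]), 0.06)
  # classification alone is exact on the noiseless label geometry
  lab <- classify_tissues(r$image, sp)
  agree <- mean(lab == r$labels)
  expect_gt(agree, 0.999)
})

test_that("volumetric MAE has its hand-computed values and flags absent regions", {
  lab <- array(0L, c(10, 10, 10))
  lab[, , 1:5] <- 1L                       # 500 brain voxels
  lab[1:5, 1, 1] <- 3L; lab[1:5, 2, 1] <- 3L # 10 vent voxels -> 2%
  lab2 <- lab
  lab2[6:10, 1, 1] <- 3L                   # 15 vent voxels -> 3%
  out <- volumetric_mae(lab2, lab, phantom_spec(), regions = c("ventricle"))
  expect_equal(unname(out$mae["ventricle"]), 1.0)
  out2 <- volumetric_mae(lab, lab, phantom_spec())
  expect_true(all(out2$mae == 0))
  expect_true("hippocampus" %in% out2$excluded)
})

test_that("Spearman utilities equal the brute-force rank definition", {
  set.seed(12)
  U <- array(runif(5^3), c(5, 5, 5))
  err <- U^2 + 3                      # monotone transform
  mask <- array(TRUE, c(5, 5, 5))
  expect_equal(uncertainty_error_correlation(U, err, mask)$rho, 1)
  expect_equal(uncertainty_error_correlation(U, max(err) - err, mask)$rho, -1)
  flat <- uncertainty_error_correlation(U * 0, err, mask)
  expect_true(flat$constant)
  expect_true(is.na(flat$rho))
  # brute force on a 5-element hand example (Pearson of ranks)
  u5 <- c(0.2, 0.9, 0.4, 0.7, 0.1)
  e5 <- c(1.0, 3.0, 4.0, 2.0, 0.5)
  Ua <- array(u5, c(5, 1, 1)); Ea <- array(e5, c(5, 1, 1))
  m <- array(TRUE, c(5, 1, 1))
  expect_equal(uncertainty_error_correlation(Ua, Ea, m)$rho,
               cor(rank(u5), rank(e5)))
  expect_error(uncertainty_error_correlation(Ua, Ea, m & FALSE), "empty mask")
})

test_that("the distance-uncertainty trend behaves on constructed inputs", {
  df_const <- data.frame(subject = rep(c("a", "b"), each = 3),
                         dB = rep(c(1, 3, 5), 2), u = 0.5)
  r <- distance_uncertainty_trend(df_const)
  expect_true(r$constant)
  expect_equal(r$rho, 0)

  # single subject with strictly increasing u: perfect rank agreement
  df_one <- data.frame(subject = "a", dB = c(1, 3, 5), u = c(0.1, 0.2, 0.35))
  expect_equal(distance_uncertainty_trend(df_one)$rho, 1)
  # pooling several such subjects keeps a strong positive correlation
  # (the per-subject zero baselines introduce ties)
  df_inc <- data.frame(subject = rep(c("a", "b"), each = 3),
                       dB = rep(c(1, 3, 5), 2),
                       u = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.9))
  expect_gt(distance_uncertainty_trend(df_inc)$rho, 0.9)

  set.seed(77)
  dfs <- do.call(rbind, lapply(1:25, function(i) {
    dB <- c(1, 3, 5, 7)
    data.frame(subject = paste0("s", i), dB = dB,
               u = 0.05 * dB + rnorm(4, 0, 0.05))
  }))
  r3 <- distance_uncertainty_trend(dfs)
  expect_gt(r3$rho, 0.4) # strong synthetic signal recovered
  expect_equal(length(r3$slopes), 25)
})

test_that("fast-progressor selection matches enumeration and the random baseline", {
  df <- data.frame(subject_id = c("a", "b", "c", "d"),
                   v_A = c(1.0, 1.0, 1.0, 1.0),
                   v_B_pred = c(0.70, 0.95, 0.80, 0.90),
                   v_B_true = c(0.75, 0.80, 0.75, 0.95))
  # predicted reductions: a .30, c .20, d .10, b .05 -> top2 {a, c}
  # true reductions: a .25, c .25, b .20, d .05 -> top2 {a, c}
  sel <- select_fast_progressors(df, 2)
  expect_setequal(sel$selected, c("a", "c"))
  expect_equal(sel$overlap, 1)
  perfect <- df; perfect$v_B_pred <- perfect$v_B_true
  expect_equal(select_fast_progressors(perfect, 3)$overlap, 1)
  expect_error(select_fast_progressors(df, 5), "exceeds")

  # random predictions: E[overlap] = S/n (hypergeometric mean)
  set.seed(5)
  n <- 100; S <- 50; reps <- 300
  ovs <- replicate(reps, {
    d <- data.frame(subject_id = sprintf("s%03d", 1:n), v_A = 1,
                    v_B_pred = runif(n), v_B_true = runif(n))
    select_fast_progressors(d, S)$overlap
  })
  se <- sd(ovs) / sqrt(reps)
  expect_lt(abs(mean(ovs) - S / n), 3 * se + 1e-3)
})

test_that("regression-ranked selection beats random on resampled phantom cohorts", {
  co <- linear_cohort_200()
  aux <- fit_linear_aux(co$table)
  tab <- co$table
  base <- tab[!duplicated(tab$subject_id), ]
  rows <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    r <- base[i, , drop = FALSE]
    idx <- which(tab$subject_id == r$subject_id)
    last <- idx[which.max(tab$age[idx])]
    data.frame(subject_id = r$subject_id, v_A = r$vol_hippocampus,
               v_B_pred = predict_volumes(aux, r, tab$age[last])[["hippocampus"]],
               v_B_true = tab$vol_hippocampus[last])
  }))
  set.seed(21)
  S <- 15; nsub <- 45
  ovs <- replicate(20, {
    sub <- rows[sample(nrow(rows), nsub), ]
    select_fast_progressors(sub, S)$overlap
  })
  # one-sided test against the hypergeometric mean S/n
  tt <- t.test(ovs, mu = S / nsub, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})
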