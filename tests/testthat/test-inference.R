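# Inference and latent average stabilization: identities on stubbed
# samplers, plumbing contracts on a tiny trained stack.

test_that("LAS summaries satisfy the zero-spread and two-point identities", {
  ident <- function(z) z # stub decoder
  Zsame <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  r <- latentcourse:::summarize_las(Zsame, codec = NULL, B = 80,
                                    decoder = ident)
  expect_equal(max(abs(r$sigma)), 0)
  expect_equal(r$u, 0)
  expect_equal(max(abs(r$U)), 0)

  a <- c(1, -2, 0.5); b <- c(2, 0, -1)
  r2 <- latentcourse:::summarize_las(rbind(a, b), codec = NULL, B = 80,
                                     decoder = ident)
  expect_equal(as.vector(r2$mu), (a + b) / 2)
  expect_equal(as.vector(r2$sigma), abs(a - b) / sqrt(2))
  expect_equal(r2$u, mean(abs(a - b) / sqrt(2))) # u is the mean of sigma
})

test_that("the uncertainty map is centered on the decoded mean, not the mean decode", {
  # nonlinear decoder distinguishes decode(mean) from mean(decode)
  dec <- function(z) array(z^3, dim = c(length(z), 1, 1))
  Z <- rbind(c(1, 2), c(3, -1), c(-2, 4))
  r <- latentcourse:::summarize_las(Z, codec = NULL, B = 70, decoder = dec)
  mu <- colMeans(Z)
  U_decoded_mean <- Reduce(`+`, lapply(1:3, function(i) (dec(Z[i, ]) - dec(mu))^2)) / 2
  mean_of_decoded <- Reduce(`+`, lapply(1:3, function(i) dec(Z[i, ]))) / 3
  U_mean_decode <- Reduce(`+`, lapply(1:3, function(i) (dec(Z[i, ]) - mean_of_decoded)^2)) / 2
  expect_equal(r$U, U_decoded_mean)
  expect_false(isTRUE(all.equal(r$U, U_mean_decode)))
  expect_equal(r$image, dec(mu))
})

test_that("uncertainty quantities are invariant to sample order and flagged at m = 1", {
  set.seed(31)
  Z <- matrix(rnorm(5 * 8), 5, 8)
  ident <- function(z) z
  r1 <- latentcourse:::summarize_las(Z, NULL, B = 75, decoder = ident)
  r2 <- latentcourse:::summarize_las(Z[sample(5), ], NULL, B = 75, decoder = ident)
  expect_equal(r1$sigma, r2$sigma)
  expect_equal(r1$u, r2$u)
  expect_equal(r1$U, r2$U)
  r3 <- latentcourse:::summarize_las(Z[1, , drop = FALSE], NULL, B = 75,
                                     decoder = ident)
  expect_false(r3$uncertainty_available)
  expect_true(is.na(r3$u))
})

test_that("LAS mean variance shrinks as 1/m with an i.i.d. stub sampler", {
  set.seed(7)
  sigma_star <- 0.8
  reps <- 300
  for (m in c(2, 8)) {
    mus <- replicate(reps, {
      Z <- matrix(rnorm(m * 4, mean = 1.5, sd = sigma_star), m, 4)
      mean(latentcourse:::summarize_las(Z, NULL, B = 70,
                                        decoder = function(z) z)$mu[1])
    })
    # mu[1] is a single latent element, so Var(mu[1]) = sigma*^2 / m
    ratio <- m * var(mus) / sigma_star^2
    expect_gt(ratio, 0.7)
    expect_lt(ratio, 1.3)
  }
})

test_that("inference is deterministic given noise and wires target covariates", {
  stack <- tiny_stack()
  co <- stack$cohort
  models <- stack$models
  row <- co$table[1, , drop = FALSE]
  x_A <- co$images[[1]]
  set.seed(3)
  zT <- rnorm(models$codec$config$latent_dim)
  z1 <- infer_once(x_A, row, row$age + 4, models, zT)
  z2 <- infer_once(x_A, row, row$age + 4, models, zT)
  expect_identical(z1, z2)
  expect_error(infer_once(x_A, row, row$age - 1, models, zT), "must exceed")
  # different target ages change the forecast volumes fed to the sampler
  v4 <- predict_volumes(models$aux, row, row$age + 4)
  v9 <- predict_volumes(models$aux, row, row$age + 9)
  expect_false(isTRUE(all.equal(v4, v9)))
  # a status override changes the prediction pathway
  z3 <- infer_once(x_A, row, row$age + 4, models, zT,
                   status_override = if (row$diagnosis == "AD") "CN" else "AD")
  expect_false(isTRUE(all.equal(z1, z3)))
})

test_that("las_predict is reproducible and predict_series reduces to it", {
  stack <- tiny_stack()
  co <- stack$cohort
  models <- stack$models
  idx <- which(co$table$subject_id == co$table$subject_id[1])
  idx <- idx[order(co$table$age[idx])]
  hist <- co$table[idx, , drop = FALSE]
  imgs <- co$images[idx]
  B <- max(hist$age) + 3

  p1 <- las_predict(imgs[[length(imgs)]], hist[nrow(hist), , drop = FALSE],
                    B, models, m = 3, seed = 5)
  p2 <- las_predict(imgs[[length(imgs)]], hist[nrow(hist), , drop = FALSE],
                    B, models, m = 3, seed = 5)
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$u, p2$u)
  expect_equal(p1$u, mean(p1$sigma)) # global uncertainty identity

  s <- predict_series(imgs, hist, B, models, mode = "single_image",
                      m = 3, seed = 9)
  s1 <- las_predict(imgs[[length(imgs)]], hist[nrow(hist), , drop = FALSE],
                    B, models, m = 3, seed = derive_seed(9, "series1"))
  expect_identical(s[[1]]$mu, s1$mu)

  expect_warning(predict_series(imgs, hist, c(B + 2, B), models, m = 2,
                                seed = 1),
                 "unordered")
})

test_that("sequence-aware mode calibrates a course model on the history", {
  stack <- tiny_stack()
  co <- stack$cohort
  models <- stack$models
  idx <- which(co$table$subject_id == co$table$subject_id[1])
  idx <- idx[order(co$table$age[idx])]
  hist <- co$table[idx, , drop = FALSE]
  imgs <- co$images[idx]
  out <- predict_series(imgs, hist, max(hist$age) + 2, models,
                        mode = "sequence_aware", m = 2, seed = 4)
  expect_s3_class(out[[1]], "prediction_result")
  expect_true(all(is.finite(out[[1]]$vhat)))
  expect_error(predict_series(imgs[1], hist[1, , drop = FALSE],
                              max(hist$age) + 2, models,
                              mode = "sequence_aware", m = 2, seed = 4),
               ">= 2 past visits")
})
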