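# Shared fixtures, built once per test session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small rendered cohort shared across codec / control / inference tests
small_cohort <- function() {
  memo("small_cohort", function() {
    simulate_cohort(10, 3, spec = phantom_spec(), seed = 42)
  })
}

# 200-subject cohort with linear (constant-rate) trajectories, used for
# auxiliary-model rate recovery
linear_cohort_200 <- function() {
  memo("linear_cohort_200", function() {
    # onset centered in the observed window keeps trajectories in the
    # constant-rate regime over every subject's visits
    simulate_cohort(200, 3, spec = phantom_spec(), seed = 1234,
                    age_range = c(66, 78),
                    onset_means = c(CN = 72, MCI = 72, AD = 72),
                    trajectory = "linear")
  })
}

# a tiny trained stack (codec + denoiser + control + aux) for plumbing
# tests; deliberately short training - quality is not asserted here
tiny_stack <- function() {
  memo("tiny_stack", function() {
    co <- small_cohort()
    codec <- train_codec(co$images,
                         codec_config(c(32, 40, 32),
                                      latent_shape = c(2, 4, 5, 4),
                                      epochs = 8, seed = 3))
    norm <- fit_covariate_norm(co$table)
    Z <- latentcourse:::encode_matrix(codec, co$images)
    covs <- covariate_matrix(co$table$age, co$table$sex, co$table$diagnosis,
                             latentcourse:::cohort_volume_matrix(co$table),
                             norm)
    schedule <- make_schedule(1000, 0.0015, 0.0205)
    den <- train_denoiser(Z, covs, schedule,
                          denoiser_config(ncol(Z), ncol(covs),
                                          steps = 300, seed = 5))
    pairs <- make_training_pairs(co, codec, norm)
    ctl <- make_control(den, cond_dim = 3 * prod(c(4, 5, 4)))
    ctl <- train_control(ctl, pairs, schedule, steps = 300, seed = 7)
    aux <- fit_linear_aux(co$table)
    list(cohort = co,
         models = progression_models(codec, ctl, aux, schedule, norm,
                                     n_steps = 25))
  })
}

expect_within <- function(x, target, rel) {
  expect_true(abs(x - target) <= rel * abs(target),
              label = sprintf("%.6g within %.0f%% of %.6g", x, 100 * rel, target))
}
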