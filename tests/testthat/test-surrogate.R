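test_that("the forward pass reproduces a hand-computed network", {
  m <- mlp_surrogate(W1 = matrix(c(1, 1), 1), b1 = 0, W2 = matrix(0.5),
                     b2 = 0.1, hidden_activation = "exponential")
  expect_equal(as.numeric(mlp_forward(m, c(0.3, 0.7))), 0.5 * exp(1) + 0.1,
               tolerance = 1e-12)

  # zero weights, identity activations: every output equals its bias
  m0 <- mlp_surrogate(W1 = matrix(0, 2, 2), b1 = c(0, 0),
                      W2 = matrix(0, 3, 2), b2 = c(1, 2, 3),
                      hidden_activation = "identity")
  expect_equal(as.vector(mlp_forward(m0, c(5, -5))), c(1, 2, 3))

  # antisymmetric first layer cancels equal inputs
  ms <- mlp_surrogate(W1 = matrix(c(1, -1), 1), b1 = 0, W2 = matrix(2),
                      b2 = 0.7, hidden_activation = "identity")
  for (a in c(-3, 0, 1.5)) {
    expect_equal(as.numeric(mlp_forward(ms, c(a, a))), 0.7)
  }
  expect_error(mlp_forward(ms, c(1, 2, 3)), "columns")
})

test_that("identity-activation networks equal their collapsed affine map", {
  set.seed(21)
  for (i in 1:15) {
    h <- sample(1:4, 1); q <- sample(1:5, 1)
    m <- random_mlp(h = h, q = q)
    A <- m$W2 %*% m$W1
    c0 <- m$W2 %*% m$b1 + m$b2
    X <- matrix(stats::rnorm(10), 5, 2)
    expect_equal(mlp_forward(m, X), X %*% t(A) + matrix(c0, 5, q, byrow = TRUE),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("min-max scaling round-trips and handles degenerate columns", {
  set.seed(2)
  x <- cbind(stats::rnorm(10), stats::runif(10, 5, 9), rep(4, 10))
  sc <- minmax_scaler(x)
  xs <- scale_minmax(x, sc)
  expect_true(all(xs[, 1:2] >= -1 & xs[, 1:2] <= 1))
  expect_true(all(xs[, 3] == 0))
  expect_equal(descale_minmax(xs, sc), x, tolerance = 1e-12)
})

test_that("accuracy metrics match their definitions", {
  m <- fit_metrics(c(2, 2, 2), c(1, 2, 3), n_params = 1)
  expect_equal(m[["chi2"]], 1.0)
  expect_equal(m[["RMSE"]], sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(m[["MBE"]], 0)
  expect_equal(m[["MPE"]], 100 / 3 * (1 - 1 / 3), tolerance = 1e-6)

  x <- c(1.2, 3.4, 2.2, 5.1)
  perfect <- fit_metrics(x, x)
  expect_equal(unname(perfect[c("RMSE", "MBE", "MPE")]), c(0, 0, 0))
  expect_equal(perfect[["r2"]], 1)

  shifted <- fit_metrics(x + 0.5, x)
  expect_equal(shifted[["MBE"]], 0.5)
  expect_equal(shifted[["RMSE"]], 0.5)
  expect_equal(shifted[["r2"]], 1)

  expect_error(fit_metrics(c(1, 2), c(0, 2)), "undefined")
  expect_error(fit_metrics(c(1, 2), c(1, 2), n_params = 2), "observations")
})

test_that("training interpolates a noiseless mixing series", {
  syn <- simulate_blend_series(noiseless_scenario())
  fit <- train_surrogate(syn, hidden = c(2, 4, 6), seed = 5, n_restarts = 10)
  r2 <- fit$report$per_output$train[, "r2"]
  expect_gte(min(r2, na.rm = TRUE), 0.999)

  # parameter recovery: held-out compositions match the mixing line
  d <- blend_dataset()
  pS <- sample_values(d, "100S/0F", blend_variables())
  pF <- sample_values(d, "0S/100F", blend_variables())
  fh <- c(0.05, 0.33, 0.77)
  pred <- mlp_forward(fit$model, cbind(100 * (1 - fh), 100 * fh))
  truth <- sapply(blend_variables(), function(v) {
    if (v == "taste_score") pmin(pmax(pS[[v]] - 1.5 * fh, 0), 5)
    else mix_property(fh, pS[[v]], pF[[v]])
  })
  rng <- apply(blend_matrix(syn, blend_variables()), 2,
               function(x) diff(range(x)))
  ok <- rng > 1e-8
  rel <- abs(pred[, ok] - truth[, ok]) / rep(rng[ok], each = length(fh))
  expect_lt(max(rel), 0.01)
})

test_that("training is reproducible given the seed", {
  syn <- simulate_blend_series(noiseless_scenario(n_points = 8))
  f1 <- train_surrogate(syn, hidden = 3, seed = 42, n_restarts = 3,
                        maxit = 150)
  f2 <- train_surrogate(syn, hidden = 3, seed = 42, n_restarts = 3,
                        maxit = 150)
  expect_identical(f1$model$W1, f2$model$W1)
  expect_identical(f1$model$W2, f2$model$W2)
})

test_that("residual analysis summarizes fit quality per output", {
  syn <- simulate_blend_series(noiseless_scenario())
  fit <- train_surrogate(syn, hidden = 4, seed = 5, n_restarts = 8)
  ra <- residual_analysis(fit$report)
  expect_setequal(ra$output, blend_variables())
  rng <- apply(blend_matrix(syn, blend_variables()), 2,
               function(x) diff(range(x)))
  expect_true(all(abs(ra$mean) < 0.05 * pmax(rng, 1)))
  expect_true(all(ra$frac_within_2sd >= 0 & ra$frac_within_2sd <= 1))

  # with known additive noise the pooled residual SD has the right order
  sigma <- 0.5
  scn <- mixing_scenario(c(a = 10, b = 2, taste_score = 4),
                         c(a = 30, b = 8, taste_score = 4),
                         n_points = 25, noise_sd = sigma, seed = 13)
  noisy <- simulate_blend_series(scn)
  fit2 <- train_surrogate(noisy, hidden = 2, seed = 5, n_restarts = 6,
                          outputs = c("a", "b"))
  ra2 <- residual_analysis(fit2$report)
  pooled <- sqrt(mean(ra2$sd^2))
  expect_gt(pooled, sigma / 2)
  expect_lt(pooled, sigma * 2)
})

test_that("surrogates survive a JSON round-trip", {
  syn <- simulate_blend_series(noiseless_scenario(n_points = 8))
  fit <- train_surrogate(syn, hidden = 3, seed = 1, n_restarts = 3,
                         maxit = 150)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_surrogate(fit$model, tmp)
  back <- read_surrogate(tmp)
  x <- cbind(c(70, 35), c(30, 65))
  expect_equal(mlp_forward(back, x), mlp_forward(fit$model, x),
               tolerance = 1e-12)
  expect_identical(back$outputs, fit$model$outputs)
})
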