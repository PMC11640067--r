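# 28-output affine surrogate on the blend variables, with simple targets
# and scales; a convenient sandbox where the objective is exactly quadratic
affine_blend_model <- function(intercepts, slopes) {
  affine_surrogate(intercepts, slopes, outputs = blend_variables())
}

flat_spec <- function(control, scales = NULL, threshold = 0,
                      weights = c(sensory = 0.20, color = 0.15,
                                  quality = 0.40, fatty_acids = 0.25),
                      resolution = 0.1) {
  if (is.null(scales)) {
    scales <- stats::setNames(rep(1, 28), blend_variables())
  }
  optimization_spec(control = control, scales = scales, weights = weights,
                    threshold = threshold, resolution = resolution)
}

test_that("the objective vanishes where predictions meet the target", {
  v <- blend_variables()
  ic <- stats::setNames(rep(2, 28), v)
  sl <- stats::setNames(rep(1, 28), v)
  m <- affine_blend_model(ic, sl)  # every output = 2 + f
  spec <- flat_spec(control = ic + 0.6)  # target met exactly at f = 0.6
  expect_equal(blend_objective(m, spec, 0.6), 0, tolerance = 1e-12)
  expect_gt(blend_objective(m, spec, 0.2), 0)

  # weights on a group with constant predictions give a flat objective
  sl2 <- sl; sl2[blend_variables("quality")] <- 0
  m2 <- affine_blend_model(ic, sl2)
  w <- c(sensory = 0, color = 0, quality = 1, fatty_acids = 0)
  spec2 <- flat_spec(control = ic + 0.25, weights = w)
  J <- blend_objective(m2, spec2, c(0, 0.3, 0.8, 1))
  expect_equal(diff(range(J)), 0, tolerance = 1e-12)
})

test_that("grid search recovers a constructed interior optimum", {
  set.seed(61)
  v <- blend_variables()
  ic <- stats::setNames(stats::runif(28, 1, 5), v)
  sl <- stats::setNames(stats::runif(28, -2, 2), v)
  m <- affine_blend_model(ic, sl)
  spec <- flat_spec(control = ic + 0.6 * sl)  # unique LS optimum at 0.6
  opt <- optimize_blend(m, spec)
  expect_true(opt$feasible)
  expect_equal(opt$f_opt, 0.6, tolerance = 1e-3 + 1e-12)

  # dense-grid oracle agrees
  fd <- seq(0, 1, by = 1e-4)
  expect_equal(fd[which.min(blend_objective(m, spec, fd))], 0.6,
               tolerance = 1e-3)
})

test_that("endpoint targets are recovered and constraints bind as expected", {
  v <- blend_variables()
  ic <- stats::setNames(rep(3, 28), v)
  sl <- stats::setNames(rep(-0.8, 28), v)
  m <- affine_blend_model(ic, sl)
  # control equals the pure-sunflower prediction; scores stay feasible
  spec <- flat_spec(control = ic, threshold = 1)
  opt <- optimize_blend(m, spec)
  expect_true(opt$feasible)
  expect_equal(opt$f_opt, 0)

  # taste declines through the threshold: optimum sits on the boundary
  ic2 <- stats::setNames(rep(4.1, 28), v)
  sl2 <- stats::setNames(rep(-0.1, 28), v)
  sl2["taste_score"] <- -2.6
  m2 <- affine_blend_model(ic2, sl2)
  spec2 <- flat_spec(control = ic2 + sl2, threshold = 2.8)  # J decreasing in f
  opt2 <- optimize_blend(m2, spec2)
  expect_true(opt2$feasible)
  expect_equal(opt2$f_opt, 0.5)  # (4.1 - 2.8) / 2.6
  expect_equal(opt2$predicted[["taste_score"]], 2.8, tolerance = 1e-9)
})

test_that("the returned optimum is never beaten by a brute-force scan", {
  set.seed(62)
  v <- blend_variables()
  for (i in 1:5) {
    ic <- stats::setNames(stats::runif(28, 0.5, 4.5), v)
    sl <- stats::setNames(stats::runif(28, -3, 3), v)
    m <- affine_blend_model(ic, sl)
    spec <- flat_spec(control = ic + stats::runif(28, -1, 1),
                      threshold = stats::runif(1, 0, 2), resolution = 0.5)
    opt <- optimize_blend(m, spec)
    f <- seq(0, 1, by = 0.005)
    J <- blend_objective(m, spec, f)
    pred <- mlp_forward(m, cbind(100 * (1 - f), 100 * f))
    feas <- apply(pred[, spec$constrained, drop = FALSE] >= spec$threshold,
                  1, all)
    if (opt$feasible && any(feas)) {
      expect_gte(min(J[feas]) + 1e-9, opt$objective)
    } else {
      expect_equal(opt$feasible, any(feas))
    }
  }
})

test_that("tightening the threshold never enlarges the feasible set", {
  v <- blend_variables()
  ic <- stats::setNames(rep(4, 28), v)
  sl <- stats::setNames(rep(0, 28), v)
  sl[blend_variables("sensory")] <- c(-1, -2, -3, -2, -1.5)
  m <- affine_blend_model(ic, sl)
  feas_count <- function(th) {
    f <- seq(0, 1, by = 0.01)
    pred <- mlp_forward(m, cbind(100 * (1 - f), 100 * f))
    sum(apply(pred[, blend_variables("sensory")] >= th, 1, all))
  }
  counts <- vapply(c(1, 2, 2.8, 3.5, 4.5), feas_count, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # fully infeasible problems report the least-violating candidate
  spec <- flat_spec(control = ic, threshold = 5)
  opt <- optimize_blend(m, spec)
  expect_false(opt$feasible)
  expect_equal(opt$f_opt, 0)  # violations grow with f
})

test_that("spec construction validates weights, threshold and scales", {
  d <- blend_dataset()
  expect_warning(optimization_spec(d), "C14:0")
  spec <- suppressWarnings(optimization_spec(d))
  expect_false("C14:0" %in% spec$active)
  expect_equal(sum(spec$weights), 1)
  expect_equal(spec$control[["deltaE"]], 0)

  expect_error(optimization_spec(d, weights = c(sensory = 0.5, color = 0.5,
                                                quality = 0.5,
                                                fatty_acids = -0.5)),
               "sum to 1")
  expect_error(suppressWarnings(optimization_spec(d, threshold = 7)),
               "\\[0, 5\\]")
  expect_error(optimization_spec(), "required")

  # an explicitly zero scale is reported by name
  sc <- stats::setNames(rep(1, 28), blend_variables())
  sc["AnV"] <- 0
  spec2 <- suppressWarnings(flat_spec(control = sc * 0 + 1, scales = sc))
  expect_false("AnV" %in% spec2$active)
})
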