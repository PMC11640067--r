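test_that("fatty-acid group sums follow the published grouping", {
  expect_equal(unname(fatty_acid_sums(sunflower_profile())[c("omega6", "omega3")]),
               c(59.71, 0.07))
  expect_equal(fatty_acid_sums(flaxseed_profile())[["PUFA"]],
               18.17 + 0.14 + 54.84)
  zero <- setNames(rep(0, 12), names(sunflower_profile()))
  expect_true(all(fatty_acid_sums(zero) == 0))
  # PUFA is exactly omega6 + omega3
  s <- fatty_acid_sums(flaxseed_profile())
  expect_identical(s[["PUFA"]], s[["omega6"]] + s[["omega3"]])
})

test_that("omega-6/omega-3 ratio matches the published blend values", {
  d <- blend_dataset()
  p80 <- sample_values(d, "80S/20F")
  expect_equal(round(omega_ratio(p80[names(p80) %in% names(sunflower_profile())]), 2),
               5.57)
  ctrl <- sample_values(d, "Control")
  expect_equal(round(omega_ratio(ctrl[names(ctrl) %in% names(sunflower_profile())]), 2),
               4.96)
  expect_equal(omega_ratio(c("C18:2n6" = 3, "C18:3n3" = 3)), 1.0)
  expect_error(omega_ratio(c("C18:2n6" = 3, "C18:3n3" = 0)), "undefined")
})

test_that("atherogenicity and thrombogenicity indices match hand-derived values", {
  d <- blend_dataset()
  getp <- function(id) {
    v <- sample_values(d, id)
    v[names(v) %in% names(sunflower_profile())]
  }
  expect_equal(round(atherogenicity_index(getp("Control")), 2), 0.04)
  # 5.97 / 90.22 for the pure sunflower oil
  expect_equal(atherogenicity_index(getp("100S/0F")), 5.97 / 90.22,
               tolerance = 1e-12)
  expect_equal(atherogenicity_index(c("C18:1" = 10)), 0)

  expect_equal(round(thrombogenicity_index(getp("100S/0F")), 2), 0.19)
  # 9.28 / 182.25 for the pure flaxseed oil
  expect_equal(thrombogenicity_index(getp("0S/100F")), 9.28 / 182.25,
               tolerance = 1e-12)
  expect_equal(thrombogenicity_index(c("C18:1" = 10, "C18:2n6" = 10)), 0)
  expect_error(atherogenicity_index(c("C16:0" = 5)), "undefined")
})

test_that("HH ratio uses total C18:1 and the palmitic+myristic denominator", {
  expect_equal(round(hh_ratio(flaxseed_profile()), 2), 18.01)
  expect_equal(round(hh_ratio(sunflower_profile()), 2), 15.08)
  expect_equal(hh_ratio(c("C16:0" = 5)), 0)
  expect_error(hh_ratio(c("C18:1" = 10)), "undefined")
})

test_that("nutritional indices are scale invariant", {
  set.seed(11)
  for (i in 1:20) {
    p <- sunflower_profile() * stats::runif(12, 0.5, 1.5)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(omega_ratio(k * p), omega_ratio(p))
    expect_equal(atherogenicity_index(k * p), atherogenicity_index(p))
    expect_equal(thrombogenicity_index(k * p), thrombogenicity_index(p))
    expect_equal(hh_ratio(k * p), hh_ratio(p))
  }
})

test_that("TOTOX reproduces the published oxidation-index column", {
  expect_equal(totox(1.60, 15.12), 18.32)
  expect_equal(totox(1.37, 3.42), 6.16)
  expect_equal(totox(0, 0), 0)
  d <- blend_dataset()
  ids <- setdiff(unique(d$sample_id), "Control")
  recomputed <- vapply(ids, function(id) {
    v <- sample_values(d, id)
    totox(v[["PV"]], v[["AnV"]])
  }, numeric(1))
  printed <- vapply(ids, function(id) sample_values(d, id)[["TOTOX"]],
                    numeric(1))
  # printed column differs only by rounding of its inputs
  expect_gte(sum(abs(recomputed - printed) <= 0.01 + 1e-12), 8)
})

test_that("Delta E is the CIE76 Euclidean distance with metric properties", {
  ctrl <- c(25.48, -1.18, 4.25)
  expect_equal(round(delta_e(c(26.50, -1.00, 3.50), ctrl), 2), 1.28)
  expect_equal(round(delta_e(c(25.14, 0.76, 8.36), ctrl), 2), 4.56)
  expect_equal(delta_e(ctrl, ctrl), 0)
  set.seed(4)
  for (i in 1:20) {
    x <- stats::rnorm(3); y <- stats::rnorm(3); z <- stats::rnorm(3)
    expect_equal(delta_e(x, y), delta_e(y, x))
    expect_lte(delta_e(x, z), delta_e(x, y) + delta_e(y, z) + 1e-12)
  }
})

test_that("sensory scores aggregate as published", {
  expect_equal(round(average_rating(3.3, 3.9, 4.1), 1), 3.8)
  expect_equal(round(average_rating(3.6, 4.1, 3.9), 1), 3.9)
  expect_equal(average_rating(0, 0, 0), 0)
  expect_equal(round(total_acceptability(3.3, 3.9, 4.1), 1), 3.8)
  expect_equal(round(total_acceptability(3.6, 4.1, 3.9), 1), 3.9)
  expect_equal(total_acceptability(5, 5, 5), 5)
  expect_error(total_acceptability(6, 1, 1), "\\[0, 5\\]")
})

test_that("total acceptability is monotone and bounded on [0, 5]", {
  set.seed(9)
  for (i in 1:25) {
    s <- stats::runif(3, 0, 5)
    base <- total_acceptability(s[1], s[2], s[3])
    expect_gte(base, 0); expect_lte(base, 5)
    d <- stats::runif(1, 0, 5 - max(s))
    expect_gte(total_acceptability(s[1] + d, s[2], s[3]), base)
    expect_gte(total_acceptability(s[1], s[2] + d, s[3]), base)
    expect_gte(total_acceptability(s[1], s[2], s[3] + d), base)
  }
})
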