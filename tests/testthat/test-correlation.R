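test_that("emptied fraction is the clamped complement of retention", {
  crv <- retention_curve(c(0, 80, 160), c(100, 14.66, 5))
  expect_equal(emptied_fraction(crv), c(0, 85.34, 95))

  noisy <- retention_curve(c(0, 80), c(104, 50))
  expect_warning(e <- emptied_fraction(noisy), "clamped")
  expect_equal(e, c(0, 50))

  # retention non-increasing => emptied non-decreasing
  mono <- noiseless_curve(0.012)
  expect_true(all(diff(emptied_fraction(mono)) >= 0))
})

test_that("two-stage fits recover exact hinge constructions", {
  # whey-like hinge at 68% emptied
  fit68 <- fit_two_stage(hinge_series(68, 1.25))
  expect_false(fit68$degenerate)
  expect_equal(fit68$breakpoint_pct, 68)
  expect_equal(fit68$stage2_slope, 1.25, tolerance = 1e-9)
  expect_equal(fit68$stage2_intercept_pct, 68, tolerance = 1e-9)
  expect_equal(fit68$r_squared_stage2, 1, tolerance = 1e-12)

  # casein-like hinge at 25%
  fit25 <- fit_two_stage(hinge_series(25, 0.8))
  expect_equal(fit25$stage2_intercept_pct, 25, tolerance = 1e-9)
  expect_equal(fit25$stage2_slope, 0.8, tolerance = 1e-9)

  # SSE grid search agrees on clean hinge data
  fit_g <- fit_two_stage(hinge_series(68, 1.25), method = "grid")
  expect_equal(fit_g$stage2_intercept_pct, 68, tolerance = 0.5)
})

test_that("two-stage fit recovers hinges under noise with a fixed seed", {
  set.seed(23)
  emptied <- seq(0, 100, by = 4)
  idx <- pmax(0, 1.25 * (emptied - 68)) + rnorm(length(emptied), 0, 0.3)
  ser <- emptying_index_series(emptied, idx, "AI", "protein")
  fit <- fit_two_stage(ser, index_floor = 1)
  expect_equal(fit$stage2_intercept_pct, 68, tolerance = 5)
  expect_equal(fit$stage2_slope, 1.25, tolerance = 0.15)
})

test_that("degenerate and malformed two-stage inputs are handled", {
  flat <- emptying_index_series(seq(0, 100, 10), rep(0, 11), "AI", "protein")
  expect_warning(fit <- fit_two_stage(flat), "degenerate")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$stage2_slope))

  expect_error(emptying_index_series(c(10, 5, 20), c(0, 0, 1), "AI",
                                     "protein"), "non-decreasing")
  expect_error(fit_two_stage(emptying_index_series(c(0, 50, 100),
                                                   c(0, 1, 2), "AI",
                                                   "protein")), ">= 4")
})

test_that("lipid-on-protein regression matches exact constructions", {
  p <- seq(0, 90, by = 10)
  ident <- protein_lipid_regression(p, p)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$r_squared, 1, tolerance = 1e-12)

  prop <- protein_lipid_regression(p, 0.79 * p)
  expect_equal(prop$slope, 0.790, tolerance = 1e-12)
  expect_equal(prop$r_squared, 1, tolerance = 1e-12)

  # symmetric inversion at perfect correlation
  fwd <- protein_lipid_regression(p, 0.5 * p)
  bwd <- protein_lipid_regression(0.5 * p, p)
  expect_equal(fwd$slope, 1 / bwd$slope, tolerance = 1e-12)

  expect_error(protein_lipid_regression(rep(10, 5), p[1:5]), "variance")
  expect_error(protein_lipid_regression(p[1:2], p[1:2]), "length")
})

test_that("noisy proportional emptying recovers the generating slope", {
  set.seed(29)
  p <- runif(50, 0, 100)
  l <- 0.9 * p + rnorm(50, 0, 2)
  fit <- protein_lipid_regression(p, l)
  expect_gte(fit$slope, 0.85); expect_lte(fit$slope, 0.95)
  expect_gt(fit$r_squared, 0.95)
})

test_that("group regressions recover per-group slopes and pool sensibly", {
  p <- seq(5, 95, by = 10)
  emptied <- data.frame(
    sample = rep(c("a1", "b1"), each = length(p)),
    protein_emptied = c(p, p),
    lipid_emptied = c(1.0 * p, 0.5 * p))
  groups <- data.frame(sample = c("a1", "b1"),
                       profile = c("whey_dominant", "casein_dominant"))
  fits <- group_regressions(emptied, groups)
  expect_equal(fits$whey_dominant$slope, 1.0, tolerance = 1e-12)
  expect_equal(fits$casein_dominant$slope, 0.5, tolerance = 1e-12)
  expect_gt(fits$overall$slope, 0.5); expect_lt(fits$overall$slope, 1.0)

  single <- group_regressions(emptied[emptied$sample == "a1", ],
                              groups[1, ])
  expect_equal(single$overall$slope, single$whey_dominant$slope)

  expect_error(group_regressions(emptied, groups[1, ]), "no profile group")
})

test_that("zero-curd simulator output gives identical macronutrient emptying", {
  ts <- run_digestion(default_formula(), digestion_protocol())
  pe <- emptied_fraction(nutrient_retention(ts, "protein"))
  le <- emptied_fraction(nutrient_retention(ts, "lipid"))
  fit <- protein_lipid_regression(pe, le)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})
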