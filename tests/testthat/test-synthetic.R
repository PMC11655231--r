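test_that("default templates encode the profile-specific study conditions", {
  tpl <- default_templates()
  expect_setequal(names(tpl), c("casein_dominant", "whey_dominant",
                                "biopolymer_whey"))
  expect_equal(tpl$casein_dominant$aggregation_onset, 15)
  expect_equal(tpl$whey_dominant$aggregation_onset, 80)
  expect_gt(tpl$whey_dominant$kappa_protein,
            tpl$casein_dominant$kappa_protein)
  expect_lt(tpl$biopolymer_whey$kappa_lipid,
            tpl$whey_dominant$kappa_lipid)

  # biopolymer profile stays coarse even in dissociating buffer
  p0 <- synth_psd_series(tpl$biopolymer_whey, 0)
  buf <- Filter(function(p) p$dispersant == "sds_edta", p0)[[1]]
  expect_gt(d43(buf)$value, 50)
})

test_that("calibrated lognormal constructions hit their target d4,3", {
  med <- lognormal_median_for_d43(1.24, 1.5)
  expect_equal(d43(lognormal_psd(med, 1.5, 1, n_bins = 150))$value, 1.24,
               tolerance = 0.005)
  fr <- calibrate_bimodal_fractions(24.74, c(1, 200), 1.5)
  expect_equal(sum(fr), 1)
  expect_equal(d43(lognormal_psd(c(1, 200), 1.5, as.numeric(fr),
                                 n_bins = 200))$value,
               24.74, tolerance = 0.01)
  expect_error(calibrate_bimodal_fractions(500, c(1, 200), 1.5),
               "not reachable")
})

test_that("synthetic PSD series coarsen after the profile-specific onset", {
  tpl <- default_templates()
  times <- c(0, 15, 40, 80, 120, 160)

  ai_of <- function(template) {
    ser <- Filter(function(p) p$dispersant == "water",
                  synth_psd_series(template, times))
    d0 <- d43(ser[[1]])
    vapply(ser, function(p) aggregation_index(d43(p), d0), numeric(1))
  }
  ai_cas <- ai_of(tpl$casein_dominant)
  ai_whey <- ai_of(tpl$whey_dominant)
  expect_gt(ai_cas[times == 160], ai_cas[times == 15])
  expect_lt(abs(ai_whey[times == 40]), 1e-9)  # before whey onset
  expect_gt(ai_cas[times == 40], 1)           # casein already aggregating
  expect_true(all(diff(ai_cas) >= -1e-9))

  # zero rates freeze the distribution
  frozen <- tpl$casein_dominant
  frozen$aggregation_rate <- 0; frozen$coalescence_rate <- 0
  ser <- synth_psd_series(frozen, times)
  v0 <- ser[[1]]$volume_density
  for (p in Filter(function(p) p$dispersant == "water", ser))
    expect_equal(p$volume_density, v0, tolerance = 1e-12)
})

test_that("synthetic retention round-trips through the fitter", {
  tpl <- default_templates()$casein_dominant
  tpl$kappa_protein <- 0.012
  clean <- synth_retention(tpl, sigma_pct = 0)
  expect_equal(clean$retained_pct, elashoff(clean$times, 100, 0.012, 1))
  fit <- fit_retention(clean)
  expect_equal(fit$kappa, 0.012, tolerance = 1e-6)

  # whey empties protein faster than casein at 80 min
  whey <- synth_retention(default_templates()$whey_dominant, sigma_pct = 0)
  cas <- synth_retention(default_templates()$casein_dominant, sigma_pct = 0)
  expect_lt(whey$retained_pct[whey$times == 80],
            cas$retained_pct[cas$times == 80])

  # noisy generation is seed-reproducible
  a <- synth_retention(tpl, sigma_pct = 2, seed = 5)
  b <- synth_retention(tpl, sigma_pct = 2, seed = 5)
  expect_identical(a$retained_pct, b$retained_pct)
})

test_that("synthetic band tables encode the hydrolysis-rate ordering", {
  tpl <- default_templates()
  times <- c(0, 15, 40, 80, 120, 160)
  res_cas <- residual_intact(synth_band_table(tpl$casein_dominant, times))
  res_whey <- residual_intact(synth_band_table(tpl$whey_dominant, times))

  # kappa-casein is hydrolyzed almost immediately in every profile
  expect_lt(res_cas["kappa_casein", times == 15], 0.2)
  expect_lt(res_whey["kappa_casein", times == 15], 0.2)
  # casein profile retains beta-LG far longer than whey retains alpha-LA
  expect_gt(res_cas["beta_LG", times == 160],
            res_whey["alpha_LA", times == 160])
  # whey-profile hydrolysis is at least as fast for caseins and alpha-LA
  for (b in c("alpha_s_casein", "beta_casein", "alpha_LA"))
    expect_gte(tpl$whey_dominant$band_rates[[b]],
               tpl$casein_dominant$band_rates[[b]])

  frozen <- tpl$casein_dominant
  frozen$band_rates[] <- 0
  bt <- synth_band_table(frozen, times)
  expect_true(all(bt$intensities == bt$intensities[, 1]))
})

test_that("full synthetic studies are deterministic and pipeline-clean", {
  s1 <- synth_study(n_per_profile = 1, seed = 99)
  s2 <- synth_study(n_per_profile = 1, seed = 99)
  expect_identical(s1$retention, s2$retention)
  expect_identical(s1$psd, s2$psd)
  expect_identical(s1$bands, s2$bands)
  expect_equal(length(s1$formulae), 3L)

  # generated PSDs are normalized per sample/time/dispersant
  key <- interaction(s1$psd$sample, s1$psd$time_min, s1$psd$dispersant)
  sums <- tapply(s1$psd$volume_frac, key, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  d <- tempfile("bundle")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  write_study_bundle(s1, d)
  res <- run_pipeline(d)
  kp <- res$fits[res$fits$nutrient == "protein", ]
  expect_true(all(kp$converged))
  expect_gt(kp$kappa[grepl("whey_dominant", kp$sample)],
            kp$kappa[grepl("casein_dominant", kp$sample)])
})
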