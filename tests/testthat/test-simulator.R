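test_that("meal initialization follows the composition bookkeeping", {
  p <- digestion_protocol()
  st <- init_state(default_formula(), p)
  expect_equal(st$chyme_mass, 110)
  expect_equal(st$protein_g, 1.70)
  expect_equal(st$lipid_g, 3.94)
  expect_equal(st$curd_protein_g, 0)
  expect_equal(st$time, 0)

  st0 <- init_state(default_formula(fat_frac = 0), p)
  expect_equal(st0$lipid_g, 0)
  expect_error(digestion_protocol(meal_mass = 0), "meal_mass")
})

test_that("secretion adds nutrient-free mass linearly in time", {
  p <- digestion_protocol()
  st <- init_state(default_formula(), p)
  st20 <- advance_state(st, 20, p)
  expect_equal(st20$chyme_mass, 120)
  expect_equal(st20$protein_g, st$protein_g)
  expect_equal(st20$lipid_g, st$lipid_g)

  tiny <- advance_state(st, 1e-6, p)
  expect_equal(tiny$chyme_mass - st$chyme_mass, 5e-7, tolerance = 1e-6)

  full <- advance_state(st, 160, p)
  expect_equal(full$chyme_mass - st$chyme_mass, 80)
  expect_error(advance_state(st, 0, p), "dt")
})

test_that("sieved emptying removes the emptiable phase proportionally", {
  p <- digestion_protocol()
  st <- advance_state(init_state(default_formula(), p), 20, p)
  ev <- empty_event(st, p)
  expect_equal(ev$aliquot$mass_g, 22)
  expect_equal(ev$aliquot$protein_g, 1.70 * 22 / 120)
  expect_equal(ev$aliquot$lipid_g, 3.94 * 22 / 120)
  expect_equal(ev$state$chyme_mass, 98)

  # nearly drained stomach: cannot remove more than present
  small <- st; small$chyme_mass <- 10
  expect_equal(empty_event(small, p)$aliquot$mass_g, 10)

  # all protein sieve-retained: no protein in the aliquot
  curded <- st; curded$curd_protein_g <- curded$protein_g
  ev2 <- empty_event(curded, p)
  expect_equal(ev2$aliquot$protein_g, 0)
  expect_gt(ev2$aliquot$mass_g, 0)

  # nothing emptiable at all
  blocked <- st
  blocked$curd_protein_g <- blocked$chyme_mass
  expect_warning(ev3 <- empty_event(blocked, p), "emptiable")
  expect_equal(ev3$aliquot$mass_g, 0)
})

test_that("full runs satisfy the closed-form zero-curd mass balance", {
  ts <- run_digestion(default_formula(), digestion_protocol())
  expect_equal(tail(ts$states$chyme_mass, 1), 110 + 80 - 8 * 22)
  expect_equal(nrow(ts$aliquots), 8)
  expect_equal(sum(ts$aliquots$mass_g), 176)

  ts0 <- run_digestion(default_formula(),
                       digestion_protocol(total_time = 0,
                                          sampling_times = numeric(0)))
  expect_equal(nrow(ts0$states), 1L)
  expect_equal(ts0$states$chyme_mass, 110)
})

test_that("mass is conserved to 1e-9 g on randomized protocols with curd", {
  set.seed(101)
  for (i in 1:25) {
    p <- digestion_protocol(
      meal_mass = runif(1, 50, 150), basal_sgf_mass = runif(1, 0, 20),
      sgf_flow = runif(1, 0, 1), enzyme_flow = runif(1, 0, 0.5),
      emptying_mass = runif(1, 5, 40),
      emptying_interval = sample(c(10, 20, 40), 1),
      total_time = sample(c(80, 160, 200), 1),
      sampling_times = numeric(0))
    f <- default_formula(curd = list(
      protein = c(runif(1, 0, 60), runif(1, 0.01, 0.2), runif(1)),
      lipid = c(runif(1, 0, 60), runif(1, 0.01, 0.2), runif(1))))
    ts <- suppressWarnings(run_digestion(f, p))
    inflow <- p$meal_mass + p$basal_sgf_mass +
      (p$sgf_flow + p$enzyme_flow) * ts$states$time
    emptied <- vapply(ts$states$time, function(t)
      sum(ts$aliquots$mass_g[ts$aliquots$time <= t + 1e-9]), numeric(1))
    expect_lt(max(abs(inflow - ts$states$chyme_mass - emptied)), 1e-9)
  }
})

test_that("retention is 100% at t = 0, proportional after emptying, non-increasing", {
  ts <- run_digestion(default_formula(), digestion_protocol())
  rp <- nutrient_retention(ts, "protein")
  expect_equal(rp$retained_pct[1], 100)
  expect_equal(rp$retained_pct[rp$times == 20], 100 * (1 - 22 / 120))
  expect_true(all(diff(rp$retained_pct) <= 1e-12))

  # zero curd: protein and lipid retention coincide with total-mass retention
  rl <- nutrient_retention(ts, "lipid")
  expect_equal(rp$retained_pct, rl$retained_pct, tolerance = 1e-12)

  expect_error(
    nutrient_retention(run_digestion(default_formula(fat_frac = 0),
                                     digestion_protocol()), "lipid"),
    "undefined|zero")
})

test_that("sieve-retained curd holds nutrients back, monotonically in the plateau", {
  full_curd <- default_formula(curd = list(protein = c(0, 10, 1),
                                           lipid = c(0, 10, 1)))
  ts <- suppressWarnings(run_digestion(full_curd, digestion_protocol()))
  rp <- nutrient_retention(ts, "protein")
  expect_true(all(rp$retained_pct > 99.99))

  plateaus <- c(0, 0.2, 0.5, 0.8)
  curves <- lapply(plateaus, function(pl) {
    f <- default_formula(curd = list(protein = c(30, 0.06, pl),
                                     lipid = c(0, 0, 0)))
    nutrient_retention(run_digestion(f, digestion_protocol()),
                       "protein")$retained_pct
  })
  for (i in seq_along(plateaus)[-1])
    expect_true(all(curves[[i]] - curves[[i - 1]] >= -1e-9))
})

test_that("pH trajectory clamps, orders by buffering capacity, and is inert without acid", {
  f <- default_formula()
  p <- digestion_protocol()
  no_acid <- run_digestion(f, p, buffering_params(acid_delivery = 0))
  expect_true(all(no_acid$states$ph == 6.8))

  huge <- run_digestion(f, p, buffering_params(buffer_capacity = 1e12))
  expect_true(all(abs(huge$states$ph - 6.8) < 1e-6))

  lo <- run_digestion(f, p, buffering_params(buffer_capacity = 5))
  hi <- run_digestion(f, p, buffering_params(buffer_capacity = 20))
  expect_true(all(hi$states$ph - lo$states$ph >= -1e-12))
  expect_gt(tail(hi$states$ph, 1), tail(lo$states$ph, 1))
  expect_true(all(diff(lo$states$ph) <= 1e-12))
  expect_true(all(lo$states$ph >= 2))
})

test_that("aliquot composition equals the emptiable-phase composition at every event", {
  f <- default_formula(curd = list(protein = c(30, 0.06, 0.4),
                                   lipid = c(40, 0.05, 0.3)))
  p <- digestion_protocol()
  ts <- run_digestion(f, p)
  # replay: concentration in each aliquot matches the pre-event emptiable phase
  for (i in seq_len(nrow(ts$aliquots))) {
    al <- ts$aliquots[i, ]
    pre <- ts$states[ts$states$time == al$time - 1, ]
    pre_sec <- advance_state(pre, 1, p)
    fp <- curd_fraction_at(f$curd_fraction_params$protein, al$time)
    emptiable <- pre_sec$chyme_mass -
      fp * pre_sec$protein_g -
      curd_fraction_at(f$curd_fraction_params$lipid, al$time) *
      pre_sec$lipid_g
    expect_equal(al$protein_g / al$mass_g,
                 (1 - fp) * pre_sec$protein_g / emptiable,
                 tolerance = 1e-9)
  }
})
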