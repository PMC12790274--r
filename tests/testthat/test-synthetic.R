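test_that("synthetic life tables behave like life tables and hit the calibration", {
  p <- default_params()
  for (sx in c("female", "male")) {
    qx <- p$life_table[[sx]]
    expect_true(all(qx >= 0 & qx <= 1))
    expect_equal(unname(qx[length(qx)]), 1)
    expect_false(is.unsorted(qx[-length(qx)])) # monotone hazard above 50
    expect_identical(attr(qx, "source"), "synthetic stand-in")
  }
  # calibration targets, checked by direct life-table summation
  expect_equal(life_expectancy(p$life_table$female, 50), 36, tolerance = 1 / 36)
  expect_equal(life_expectancy(p$life_table$male, 50), 31, tolerance = 1 / 31)

  # degenerate hazard: constant qx (horizon forced to 1)
  flat <- make_life_table("female", list(makeham = 0.01, gompertz_scale = 0,
                                         gompertz_shape = 0, reference_age = 50))
  expect_equal(unname(unique(flat[-length(flat)])), rate_to_prob(0.01))
})

test_that("population generation is weight-faithful, restrictable and reproducible", {
  p <- default_params()
  expect_equal(nrow(make_population(0, p$population, 1)), 0)

  pop1 <- p$population
  pop1$sex_shares <- c(female = 1, male = 0)
  expect_true(all(make_population(500, pop1, 1)$sex == "female"))

  n <- 1e5
  roster <- make_population(n, p$population, 1)
  expect_true(all(roster$age >= 50 & roster$age < 105))
  # 5-yr band frequencies match the sampling weights within 3 SE
  w <- p$population$age_weights / sum(p$population$age_weights)
  band <- findInterval(roster$age, p$population$age_band_lower)
  for (b in seq_along(w)[w > 1e-4]) {
    se <- sqrt(w[b] * (1 - w[b]) / n)
    expect_lt(abs(mean(band == b) - w[b]), 3 * se + 1e-12)
  }
  expect_identical(roster, make_population(n, p$population, 1))
  expect_false(identical(roster$age, make_population(n, p$population, 2)$age))

  old <- make_population(2000, p$population, 1, min_age = 70)
  expect_true(all(old$age >= 70))
})

test_that("osteoporosis assignment matches fixed and age-specific prevalence", {
  p <- default_params()
  n <- 1e5
  roster <- make_population(n, p$population, 3)
  flags <- assign_osteoporosis(roster, p$prevalence, 3)
  for (sx in c("female", "male")) {
    target <- p$prevalence$fixed[[sx]]
    sel <- roster$sex == sx
    se <- sqrt(target * (1 - target) / sum(sel))
    expect_lt(abs(mean(flags[sel]) - target), 3 * se)
  }
  zero <- p$prevalence; zero$fixed[] <- 0
  expect_false(any(assign_osteoporosis(roster, zero, 3)))

  asp <- p$prevalence; asp$mode <- "age_specific"
  flags2 <- assign_osteoporosis(roster, asp, 3)
  sel <- roster$sex == "male" & roster$age < 60
  se <- sqrt(0.035 * 0.965 / sum(sel))
  expect_lt(abs(mean(flags2[sel]) - 0.035), 3 * se)
  sel <- roster$sex == "female" & roster$age >= 70
  se <- sqrt(0.685 * 0.315 / sum(sel))
  expect_lt(abs(mean(flags2[sel]) - 0.685), 3 * se)

  expect_identical(flags, assign_osteoporosis(roster, p$prevalence, 3))
})

test_that("post-fracture mortality stand-in has the documented structure", {
  m <- default_post_fracture_mortality()
  expect_equal(m$attribution, 0.25)
  # NHNV carries no excess at any time: not a column of the excess matrix
  expect_identical(colnames(m$first_year_excess), c("hip", "vertebral"))
  expect_true(all(m$first_year_excess > 0))
  expect_identical(m$source, "synthetic stand-in")
  # long-term hazard ratio decays to exactly 1
  expect_equal(osteoscreen:::longterm_mortality_hr(30, m), 1)
  expect_equal(osteoscreen:::longterm_mortality_hr(Inf, m), 1)
  hr <- osteoscreen:::longterm_mortality_hr(1:12, m)
  expect_true(all(diff(hr) <= 0) && all(hr >= 1))
})

test_that("subsequent-fracture multipliers follow the stand-in table", {
  m <- default_subsequent_multipliers()
  expect_equal(subsequent_multiplier(c(1, 7, 30), 0, m), c(1, 1, 1))
  expect_equal(subsequent_multiplier(1, 1, m), 2.0)
  expect_equal(subsequent_multiplier(4, 1, m), 1.5)
  expect_equal(subsequent_multiplier(10, 1, m), 1.2)
  expect_equal(subsequent_multiplier(1, 3, m), 2.4)
  expect_equal(subsequent_multiplier(1, 50, m), 4.0) # cap
  for (k in 1:5) {
    mk <- subsequent_multiplier(c(0, 1, 2, 3, 5, 6, 40), k, m)
    expect_true(all(diff(mk) <= 0))
  }
  expect_true(all(diff(subsequent_multiplier(1, 1:8, m)) >= 0))
})

test_that("rng child streams are stable and label-isolated", {
  expect_identical(osteoscreen:::stream_runif(5, 1, "death", 3),
                   osteoscreen:::stream_runif(5, 1, "death", 3))
  expect_false(identical(osteoscreen:::stream_runif(5, 1, "death", 3),
                         osteoscreen:::stream_runif(5, 1, "frac_hip", 3)))
  expect_false(identical(osteoscreen:::stream_runif(5, 1, "death", 3),
                         osteoscreen:::stream_runif(5, 1, "death", 4)))
  expect_true(child_seed(1, "x") >= 0 && child_seed(1, "x") < 2^31)
  expect_true(child_seed(2^31 - 1, "psa_inner", 200) < 2^31)
})
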