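test_that("packaged defaults validate and reproduce the source data table", {
  p <- default_params()
  expect_length(validate_params(p), 0)

  # screening and cascade block
  expect_equal(p$test$sensitivity, 0.8616)
  expect_equal(p$test$specificity, 0.7419)
  expect_equal(p$test$unit_cost, 15000)
  expect_equal(p$cascade$p_dxa_uptake, 0.60)
  expect_equal(p$cascade$p_treat_init, 0.50)
  expect_equal(p$cascade$dxa_cost, 50000)

  # full incidence and T-score relative-risk tables
  expect_equal(unname(p$incidence$female["hip", ]), c(0.0003, 0.0007, 0.0030, 0.0136))
  expect_equal(unname(p$incidence$female["vertebral", ]), c(0.0021, 0.0070, 0.0215, 0.0456))
  expect_equal(unname(p$incidence$female["nhnv", ]), c(0.0053, 0.0092, 0.0123, 0.0165))
  expect_equal(unname(p$incidence$male["hip", ]), c(0.0001, 0.0003, 0.0013, 0.0061))
  expect_equal(unname(p$incidence$male["vertebral", ]), c(0.0007, 0.0025, 0.0076, 0.0161))
  expect_equal(unname(p$incidence$male["nhnv", ]), c(0.0016, 0.0027, 0.0037, 0.0055))
  expect_equal(unname(p$tscore_rr$female["hip", ]), c(5.659, 3.390, 2.250, 1.570))
  expect_equal(unname(p$tscore_rr$male["hip", ]), c(9.817, 5.887, 4.334, 2.307))
  expect_equal(unname(p$tscore_rr$female["vertebral", ]), c(2.680, 2.176, 1.772, 1.514))
  expect_equal(unname(p$tscore_rr$male["vertebral", ]), c(3.542, 2.990, 2.702, 2.144))
  expect_equal(unname(p$tscore_rr$female["nhnv", ]), c(2.250, 1.902, 1.610, 1.416))
  expect_equal(unname(p$tscore_rr$male["nhnv", ]), c(2.815, 2.457, 2.264, 1.879))

  # costs and utilities
  expect_equal(unname(p$costs$fracture_first_year[, "female"]),
               c(17444178, 5281372, 6494541))
  expect_equal(unname(p$costs$fracture_first_year[, "male"]),
               c(19718093, 5969819, 7341129))
  # male fracture costs are ~13% above female, per site
  expect_equal(unname(p$costs$fracture_first_year[, "male"] /
                        p$costs$fracture_first_year[, "female"]),
               rep(1.13, 3), tolerance = 0.005)
  expect_equal(p$costs$nursing_home_daily_cost, 8103)
  expect_equal(p$costs$physician_visit_cost, 17942)
  expect_equal(p$costs$pharmacy_visit_cost, 8748)
  expect_equal(p$utility$baseline,
               c(0.940, 0.930, 0.910, 0.880, 0.850, 0.790, 0.750, 0.820, 0.900))
  expect_equal(unname(p$utility$post_fracture[, "first_year"]), c(0.55, 0.68, 0.79))
  expect_equal(unname(p$utility$post_fracture[, "subsequent"]), c(0.86, 0.85, 0.95))
  # hip first-year decrement worst, then vertebral, then NHNV
  expect_true(all(diff(p$utility$post_fracture[, "first_year"]) > 0))

  # drugs and mix
  expect_equal(p$drugs$alendronate$rr, c(hip = 0.67, vertebral = 0.45, nhnv = 0.81))
  expect_equal(p$drugs$denosumab$rr, c(hip = 0.60, vertebral = 0.32, nhnv = 0.80))
  expect_equal(p$drugs$alendronate$annual_cost, 244512)
  expect_equal(p$drugs$denosumab$annual_cost, 247520)
  expect_equal(p$drugs$alendronate$persistence[1:2], c(0.732, 0.336))
  expect_equal(p$drugs$denosumab$persistence[c(1, 3)], c(0.67, 0.35))
  expect_equal(unname(p$mix$shares), c(0.672, 0.328))
  expect_equal(p$mix$max_duration_years, 5L)

  # prevalence and economics
  expect_equal(unname(p$prevalence$fixed), c(0.373, 0.075))
  expect_equal(unname(p$prevalence$age_specific["female", ]), c(0.154, 0.366, 0.685))
  expect_equal(unname(p$prevalence$age_specific["male", ]), c(0.035, 0.075, 0.180))
  expect_equal(p$econ$discount_rate, 0.045)
  expect_equal(as.integer(p$econ$horizon_age), 105L)
})

test_that("rate_to_prob matches the closed form and its hazard algebra", {
  expect_equal(rate_to_prob(0, 1), 0)
  expect_equal(rate_to_prob(0.0136, 1), 0.01350793782, tolerance = 1e-9)
  expect_equal(rate_to_prob(10, 1), 0.9999546001, tolerance = 1e-9)
  expect_lt(rate_to_prob(10, 1), 1)
  expect_error(rate_to_prob(-0.1), "non-negative")

  # splitting the interval composes multiplicatively on survival
  for (r in c(0.001, 0.05, 0.4, 2)) for (ab in list(c(1, 1), c(0.3, 1.7))) {
    expect_equal(rate_to_prob(r, sum(ab)),
                 1 - (1 - rate_to_prob(r, ab[1])) * (1 - rate_to_prob(r, ab[2])))
  }
  # monotone in rate
  expect_true(all(diff(rate_to_prob(seq(0, 5, by = 0.1), 1)) > 0))
})

test_that("baseline utility interpolates knots and plateaus after 90", {
  expect_equal(baseline_utility(70), 0.850)
  expect_equal(baseline_utility(52.5), 0.935)
  expect_equal(baseline_utility(100), 0.900)
  expect_equal(baseline_utility(c(50, 90)), c(0.940, 0.900))
  expect_error(baseline_utility(49), ">= 50")
})

test_that("discount factor is the standard compound factor and multiplicative", {
  expect_equal(discount_factor(0), 1)
  expect_equal(discount_factor(10, 0.045), 0.643927682, tolerance = 1e-9)
  expect_equal(discount_factor(7, 0), 1)
  for (t1 in c(0.5, 3)) for (t2 in c(1, 10.25))
    expect_equal(discount_factor(t1 + t2), discount_factor(t1) * discount_factor(t2))
  expect_error(discount_factor(-1), "non-negative")
})

test_that("configs merge over defaults, reject bad keys and honour overrides", {
  expect_equal(unclass(load_config(NULL)), unclass(default_params()))

  cfg <- tempfile(fileext = ".json")
  writeLines('{"cascade": {"p_dxa_uptake": 0.8}}', cfg)
  p <- load_config(cfg)
  base <- default_params()
  expect_equal(p$cascade$p_dxa_uptake, 0.8)
  p$cascade$p_dxa_uptake <- base$cascade$p_dxa_uptake
  expect_equal(unclass(p), unclass(base)) # nothing else moved

  yml <- tempfile(fileext = ".yaml")
  writeLines("test:\n  sensitivity: 0.9", yml)
  expect_equal(load_config(yml)$test$sensitivity, 0.9)

  bad <- tempfile(fileext = ".json")
  writeLines('{"nonsense_key": 1}', bad)
  expect_error(load_config(bad), "unknown config key")

  oob <- tempfile(fileext = ".json")
  writeLines('{"test": {"sensitivity": 1.2}}', oob)
  expect_error(load_config(oob), "sensitivity")

  p2 <- load_config(NULL, overrides = list("cascade.p_dxa_uptake" = 0.8))
  expect_equal(p2$cascade$p_dxa_uptake, 0.8)
  expect_error(load_config(NULL, overrides = list("no.such.path" = 1)),
               "unknown parameter path")
})

test_that("validation reports named violations for broken invariants", {
  p <- default_params()
  p$drugs$alendronate$persistence <- c(0.5, 0.6, 0.6, 0.6, 0.6)
  expect_match(validate_params(p), "persistence non-increasing", all = FALSE)

  p <- default_params()
  p$mix$shares <- c(alendronate = 0.7, denosumab = 0.4)
  expect_match(validate_params(p), "shares must sum to 1", all = FALSE)

  p <- default_params()
  p$life_table$female[10] <- 2
  expect_match(validate_params(p), "life_table", all = FALSE)

  # property-style fuzz: breaking any probability bound is caught
  paths <- list(c("test", "sensitivity"), c("cascade", "p_treat_init"),
                c("mortality", "attribution"),
                c("costs", "nursing_home_prob_after_hip"))
  for (pa in paths) {
    p <- default_params()
    p[[pa[1]]][[pa[2]]] <- 1.5
    expect_gt(length(validate_params(p)), 0)
  }
})
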