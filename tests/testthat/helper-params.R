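# shared fixture builders (all fixtures are constructed in code)

# history-independent settings with a degenerate cascade: everyone
# osteoporotic is flagged, confirmed and treated (single drug, full
# persistence); no subsequent-fracture risk, no excess mortality, no
# post-fracture utility loss, no nursing home.  Valid input for the
# deterministic cohort recursion.
simplified_params <- function(drug = "alendronate") {
  p <- default_params()
  p$subsequent$recent <- 1
  p$subsequent$mid <- 1
  p$subsequent$late <- 1
  p$subsequent$per_extra_prior <- 0
  p$mortality$attribution <- 0
  p$utility$post_fracture[] <- 1
  p$costs$nursing_home_prob_after_hip <- 0
  p$test$sensitivity <- 1
  p$test$specificity <- 1
  p$cascade$p_dxa_uptake <- 1
  p$cascade$p_treat_init <- 1
  for (d in names(p$drugs)) p$drugs[[d]]$persistence <- rep(1, 5)
  shares <- stats::setNames(as.numeric(names(p$mix$shares) == drug),
                            names(p$mix$shares))
  p$mix$shares <- shares
  p
}

# parameters with the screening arm made inert: nobody flagged, no AI cost
no_effect_params <- function(ai_cost = 0) {
  p <- default_params()
  p$test$sensitivity <- 0
  p$test$specificity <- 1
  p$test$unit_cost <- ai_cost
  p
}

# small roster with fixed composition for engine tests
test_roster <- function(n, age = 65, sex = "female") {
  data.frame(age = rep(as.integer(age), n),
             sex = factor(rep(sex, n), levels = c("female", "male")))
}

# minimal hand-built arm_outcome pair for outcome-algebra tests
fake_arms <- function(cost_s, qaly_s, cost_c, qaly_c, id = "fake") {
  mk <- function(cost, qaly) {
    n <- length(cost)
    structure(list(
      n = n, cohort_id = id,
      mean = c(cost = mean(cost), qaly = mean(qaly), ly = 0, fractures = 0),
      se = c(cost = 0, qaly = 0, ly = 0, fractures = 0),
      ind = list(cost = cost, qaly = qaly, ly = rep(0, n),
                 fractures = rep(0, n))), class = "arm_outcome")
  }
  list(screening = mk(cost_s, qaly_s), no_screening = mk(cost_c, qaly_c))
}
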