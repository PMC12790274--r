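# Deterministic cohort recursion used as an independent oracle for the
# microsimulation.  Valid only for history-independent settings: no
# subsequent-fracture multipliers, no post-fracture excess mortality, no
# post-fracture utility loss, no nursing-home admission, deterministic
# (all-1) persistence, and a degenerate screening cascade (probabilities in
# {0, 1}, single drug).  Under those settings every individual's expected
# trajectory factorises over age, and expected discounted costs, QALYs,
# life-years and fracture counts follow by forward summation over the life
# table.

#' Expected cohort outcomes by deterministic forward recursion
#'
#' Computes, for each arm, the exact expected discounted cost, QALYs,
#' life-years and lifetime fracture count implied by the model, for
#' history-independent settings (see Details).  Used in tests as the oracle
#' against which microsimulation means are checked.
#'
#' @details The function refuses to run (with an error) unless the parameter
#' bundle is history-independent: subsequent-fracture multipliers identically
#' 1, attribution or all excess mortality 0, post-fracture utility
#' multipliers 1, nursing-home probability 0, persistence identically 1, all
#' cascade probabilities in `{0, 1}`, and a single-drug treatment mix.
#'
#' @param roster data frame of entry `age`/`sex`.
#' @param osteo logical osteoporosis flags.
#' @param params history-independent `osteo_params` bundle.
#' @return list with `screening` and `no_screening`, each a named vector
#'   `c(cost, qaly, ly, fractures)` of per-person expected values.
#' @export
cohort_expected_value <- function(roster, osteo, params) {
  sub <- params$subsequent
  if (any(subsequent_multiplier(c(0, 1, 4, 10), 1:4, sub) != 1))
    stop("oracle requires subsequent-fracture multipliers identically 1")
  mt <- params$mortality
  if (mt$attribution != 0 &&
      (any(mt$first_year_excess > 0) || mt$longterm_hr0 != 1))
    stop("oracle requires no post-fracture excess mortality")
  if (any(params$utility$post_fracture != 1))
    stop("oracle requires post-fracture utility multipliers of 1")
  if (params$costs$nursing_home_prob_after_hip != 0)
    stop("oracle requires nursing_home_prob_after_hip = 0")
  for (d in params$drugs)
    if (any(d$persistence[seq_len(params$mix$max_duration_years - 1L)] != 1))
      stop("oracle requires deterministic (all-1) persistence")
  probs <- c(params$test$sensitivity, params$test$specificity,
             params$cascade$p_dxa_uptake, params$cascade$p_treat_init)
  if (!all(probs %in% c(0, 1)))
    stop("oracle requires cascade probabilities in {0, 1}")
  if (!any(params$mix$shares == 1))
    stop("oracle requires a single-drug treatment mix")
  drug <- params$drugs[[names(params$mix$shares)[params$mix$shares == 1]]]

  groups <- unique(data.frame(age = roster$age, sex = as.character(roster$sex),
                              osteo = osteo))
  wts <- numeric(nrow(groups))
  key_all <- paste(roster$age, roster$sex, osteo)
  key_grp <- paste(groups$age, groups$sex, groups$osteo)
  tab <- table(key_all)
  wts <- as.numeric(tab[key_grp]) / nrow(roster)

  out <- list()
  for (arm in c("screening", "none")) {
    acc <- c(cost = 0, qaly = 0, ly = 0, fractures = 0)
    for (g in seq_len(nrow(groups))) {
      e <- expected_individual(groups$age[g], groups$sex[g], groups$osteo[g],
                               params, drug, arm)
      acc <- acc + wts[g] * e
    }
    out[[if (arm == "screening") "screening" else "no_screening"]] <- acc
  }
  out
}

expected_individual <- function(age0, sex, osteo, params, drug, arm) {
  ec <- params$econ
  horizon <- as.integer(ec$horizon_age)
  r <- ec$discount_rate
  cs <- params$costs
  treated <- arm == "screening" && osteo &&
    params$test$sensitivity == 1 && params$cascade$p_dxa_uptake == 1 &&
    params$cascade$p_treat_init == 1
  max_dur <- params$mix$max_duration_years

  upfront <- 0
  if (arm == "screening") {
    flagged_p <- if (osteo) params$test$sensitivity else 1 - params$test$specificity
    upfront <- params$test$unit_cost +
      flagged_p * params$cascade$p_dxa_uptake * params$cascade$dxa_cost
  }
  annual_tx <- drug$annual_cost +
    drug$monitoring$physician_visits_per_year * cs$physician_visit_cost +
    drug$monitoring$pharmacy_visits_per_year * cs$pharmacy_visit_cost +
    drug$monitoring$dxa_per_year * cs$dxa_cost
  ae1 <- (drug$ae$gp_visits_first_6mo + drug$ae$gp_visits_per_subsequent_6mo) *
    (cs$physician_visit_cost + drug$ae$ppi_cost_per_episode)
  ae2 <- 2 * drug$ae$gp_visits_per_subsequent_6mo *
    (cs$physician_visit_cost + drug$ae$ppi_cost_per_episode)

  cost <- upfront; qaly <- 0; ly <- 0; fr <- 0
  S <- 1
  for (t in 0:(horizon - 1 - age0)) { # hard horizon: no accrual at age 105
    a <- age0 + t
    qx <- lookup_qx(a, sex, params)
    S_next <- S * (1 - qx)
    at_risk <- S
    died <- S - S_next
    credit <- S_next + 0.5 * died
    df <- (1 + r)^(-(t + 0.5))

    # deterministic treatment schedule: on treatment for cycles 0..max_dur-1,
    # forced stop at the boundary, then waning
    if (treated) {
      if (t < max_dur) {
        rr_eff <- drug$rr[SITES]
        tx <- annual_tx + if (t == 0) ae1 else ae2
      } else {
        ys_stop <- t - max_dur
        rr_eff <- treatment_rr(SITES, drug, on_treatment = FALSE,
                               years_on_treatment = max_dur,
                               years_since_stop = ys_stop)
        names(rr_eff) <- SITES
        tx <- 0
      }
    } else {
      rr_eff <- c(hip = 1, vertebral = 1, nhnv = 1)
      tx <- 0
    }

    band <- min(findInterval(a, AGE_BAND_LOWER), 4L)
    p_site <- vapply(SITES, function(s) {
      rate <- params$incidence[[sex]][s, band] *
        (if (osteo) params$tscore_rr[[sex]][s, band] else 1) * rr_eff[[s]]
      1 - exp(-rate)
    }, numeric(1))
    fr <- fr + at_risk * sum(p_site)
    cost <- cost + df * (at_risk * sum(p_site * cs$fracture_first_year[, sex]) +
                           tx * credit)
    u <- baseline_utility(a, params$utility)
    qaly <- qaly + df * u * credit
    ly <- ly + credit
    S <- S_next
    if (S < 1e-12) break
  }
  c(cost = cost, qaly = qaly, ly = ly, fractures = fr)
}
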