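# Individual-level Markov microsimulation with annual cycles.
#
# Cycle order: (1) fracture events sampled independently per site,
# (2) death sampled (including this cycle's first-year excess for hip or
# vertebral events), (3) cost accrual (per-event fracture costs in full;
# ongoing nursing-home and treatment costs with half-credit in the cycle of
# death), (4) utility accrual (most-severe-site multiplier only; half-cycle
# credit at death), (5) mid-cycle discounting, (6) clock advancement.
#
# Both arms regenerate identical per-cycle natural-history uniforms from
# labelled child streams (common random numbers): treatment shifts event
# thresholds, never the draws.

SEVERITY <- c(hip = 1L, vertebral = 2L, nhnv = 3L) # smaller = more severe

#' Effective treatment relative risk with post-stop waning
#'
#' On treatment the drug's relative risk applies directly.  After stopping,
#' the effect wanes: linearly over the time spent on treatment
#' (`linear_over_treatment_duration`, alendronate-like), linearly over one
#' year (`linear_over_one_year`, denosumab-like, capturing rebound), or as a
#' step at one year (`step_at_one_year`).  The effective RR never exceeds 1.
#'
#' @param site `"hip"`, `"vertebral"` or `"nhnv"`.
#' @param drug a drug profile (`params$drugs$alendronate`, ...).
#' @param on_treatment logical; vectorised with the clock arguments.
#' @param years_on_treatment years spent on treatment (at stop, if stopped).
#' @param years_since_stop years since discontinuation (0 in the first cycle
#'   after the stop boundary).
#' @return effective relative risk in `(0, 1]`.
#' @export
treatment_rr <- function(site, drug, on_treatment = TRUE,
                         years_on_treatment = 0, years_since_stop = 0) {
  if (is.null(drug)) stop("no drug assigned")
  rr <- unname(drug$rr[site])
  if (any(is.na(rr))) stop("unknown site: ", paste(site, collapse = ", "))
  w <- switch(drug$waning,
    linear_over_treatment_duration =
      pmax(0, 1 - years_since_stop / pmax(years_on_treatment, 1e-12)),
    linear_over_one_year = pmax(0, 1 - years_since_stop),
    step_at_one_year = as.numeric(years_since_stop < 1),
    stop("unknown waning rule: ", drug$waning))
  w <- ifelse(on_treatment, 1, w)
  pmin(1, 1 - (1 - rr) * w)
}

#' Conditional discontinuation probability at a treatment-year boundary
#'
#' With annual persistence `S(k)` (fraction still on treatment at the end of
#' year `k`, `S(0) = 1`), the probability of stopping at the boundary after
#' year `k`, conditional on having persisted so far, is `1 - S(k)/S(k-1)`.
#'
#' @param drug a drug profile.
#' @param year_k completed treatment year (1-based); vectorised.
#' @return conditional stop probability in `[0, 1]`.
#' @export
discontinuation_prob <- function(drug, year_k) {
  S <- c(1, drug$persistence)
  k <- pmin(year_k, length(drug$persistence))
  pmin(1, pmax(0, 1 - S[k + 1L] / S[k]))
}

#' Apply one persistence boundary to an individual treatment state
#'
#' @param state list with `on_treatment`, `years_on_treatment`,
#'   `years_since_stop` (NA while on treatment).
#' @param drug a drug profile.
#' @param mix treatment-mix block (for `max_duration_years`).
#' @param u uniform draw deciding discontinuation.
#' @return updated state; `years_since_stop` starts at 0 on the boundary
#'   where discontinuation occurs.
#' @export
update_persistence <- function(state, drug, mix, u = stats::runif(1)) {
  stopifnot(isTRUE(state$on_treatment))
  k <- state$years_on_treatment + 1
  state$years_on_treatment <- k
  stop_now <- k >= mix$max_duration_years || u < discontinuation_prob(drug, k)
  if (stop_now) {
    state$on_treatment <- FALSE
    state$years_since_stop <- 0
  }
  state
}

#' Annual fracture probability for one risk profile
#'
#' Baseline incidence (by sex, site and 10-year age band) times the T-score
#' relative risk if osteoporotic, times the subsequent-fracture multiplier,
#' times the effective treatment relative risk, converted with
#' [rate_to_prob()].
#'
#' @param age,sex,site risk profile; `sex` is `"female"`/`"male"`.
#' @param osteoporotic logical.
#' @param years_since_last years since the most recent fracture (Inf if none).
#' @param n_prior number of prior fractures.
#' @param rr_treatment effective treatment relative risk (1 if untreated).
#' @param params `osteo_params` bundle.
#' @return probability of at least one fracture at `site` this year.
#' @export
annual_fracture_prob <- function(age, sex, site, osteoporotic = FALSE,
                                 years_since_last = Inf, n_prior = 0,
                                 rr_treatment = 1, params = default_params()) {
  band <- age_band_index(age)
  rate <- params$incidence[[sex]][site, band] *
    (if (osteoporotic) params$tscore_rr[[sex]][site, band] else 1) *
    subsequent_multiplier(years_since_last, n_prior, params$subsequent) *
    rr_treatment
  rate_to_prob(rate, 1)
}

#' Annual death probability given fracture history
#'
#' Baseline `qx` plus attribution-scaled excess: the first-year excess
#' probability in the cycle of a hip/vertebral fracture, or
#' `qx * (HR(years since) - 1)` for a prior hip/vertebral fracture.  NHNV
#' fractures carry no excess.  Capped at 1.
#'
#' @param age,sex demographics.
#' @param fracture_this_cycle `"hip"`, `"vertebral"`, other site label, or
#'   `NA` for none.
#' @param years_since_hv years since the last hip/vertebral fracture (Inf if
#'   none).
#' @param params `osteo_params` bundle.
#' @return death probability in `[0, 1]`.
#' @export
annual_death_prob <- function(age, sex, fracture_this_cycle = NA,
                              years_since_hv = Inf, params = default_params()) {
  qx <- lookup_qx(age, sex, params)
  mt <- params$mortality
  excess <- if (!is.na(fracture_this_cycle) &&
                fracture_this_cycle %in% colnames(mt$first_year_excess)) {
    mt$first_year_excess[sex, fracture_this_cycle]
  } else if (is.finite(years_since_hv)) {
    qx * (longterm_mortality_hr(years_since_hv, mt) - 1)
  } else 0
  min(1, qx + mt$attribution * excess)
}

lookup_qx <- function(age, sex, params) {
  qx <- params$life_table[[sex]]
  idx <- pmin(pmax(age, 50L) - 49L, length(qx))
  unname(qx[idx])
}

# ---- vectorised cohort engine ----------------------------------------------

# Simulate every roster member under one arm.  Returns per-individual
# accumulators.  All random draws come from (seed, label, cycle) child
# streams of full cohort length, so the two arms see identical uniforms.
simulate_arm <- function(roster, osteo, params, arm = c("screening", "none"),
                         seed = 1) {
  arm <- match.arg(arm)
  n <- nrow(roster)
  stopifnot(n > 0, length(osteo) == n)
  age0 <- as.integer(roster$age)
  is_male <- roster$sex == "male"
  sex_idx <- ifelse(is_male, 2L, 1L)

  ec <- params$econ
  r <- ec$discount_rate
  horizon <- as.integer(ec$horizon_age)
  mt <- params$mortality
  cs <- params$costs
  sub <- params$subsequent
  ndrug <- length(params$drugs)
  drug_names <- names(params$drugs)

  # per-drug precomputations
  rr_drug <- sapply(params$drugs, function(d) d$rr[SITES])        # 3 x ndrug
  annual_tx_cost <- sapply(params$drugs, function(d) {
    d$annual_cost +
      d$monitoring$physician_visits_per_year * cs$physician_visit_cost +
      d$monitoring$pharmacy_visits_per_year * cs$pharmacy_visit_cost +
      d$monitoring$dxa_per_year * cs$dxa_cost
  })
  ae_year1 <- sapply(params$drugs, function(d)
    (d$ae$gp_visits_first_6mo + d$ae$gp_visits_per_subsequent_6mo) *
      (cs$physician_visit_cost + d$ae$ppi_cost_per_episode))
  ae_later <- sapply(params$drugs, function(d)
    2 * d$ae$gp_visits_per_subsequent_6mo *
      (cs$physician_visit_cost + d$ae$ppi_cost_per_episode))

  # incidence / t-score RR / fracture cost lookups as [site, band, sex] arrays
  inc <- array(c(params$incidence$female, params$incidence$male), c(3, 4, 2))
  tsr <- array(c(params$tscore_rr$female, params$tscore_rr$male), c(3, 4, 2))
  fcost <- cs$fracture_first_year # 3 x 2 (site x sex)
  fy_ex <- mt$first_year_excess   # 2 x 2 (sex x site hip/vertebral)
  qx_tab <- cbind(lookup_qx(50:horizon, "female", params),
                  lookup_qx(50:horizon, "male", params))
  u_tab <- baseline_utility(50:horizon, params$utility)
  fy_mult <- params$utility$post_fracture[, "first_year"]
  sub_mult <- params$utility$post_fracture[, "subsequent"]

  # screening cascade at entry (screening arm only); upfront costs at t = 0
  if (arm == "screening") {
    cas <- screen_cohort(osteo, params, seed)
    treated <- cas$treated
    drug_id <- ifelse(treated, match(as.character(cas$drug), drug_names), 0L)
    drug_id[is.na(drug_id)] <- 0L
    upfront <- cas$upfront_cost
  } else {
    treated <- rep(FALSE, n)
    drug_id <- rep(0L, n)
    upfront <- rep(0, n)
  }

  # state
  alive <- rep(TRUE, n)
  age <- age0
  on_tx <- treated
  yrs_on <- rep(0L, n)            # completed treatment years
  stopped <- rep(FALSE, n)
  yrs_stop <- rep(0, n)           # years since stop (valid when stopped)
  yrs_on_at_stop <- rep(0, n)
  n_prior <- rep(0L, n)
  ys_last <- rep(Inf, n)          # years since last fracture, any site
  ys_last_hv <- rep(Inf, n)       # years since last hip/vertebral fracture
  worst_hist <- rep(0L, n)        # severity code of worst site ever (0 none)
  in_nh <- rep(FALSE, n)

  disc_cost <- upfront            # t = 0, undiscounted
  disc_qaly <- rep(0, n)
  life_years <- rep(0, n)
  frac_counts <- matrix(0L, n, 3, dimnames = list(NULL, SITES))

  nh_annual <- 365 * cs$nursing_home_daily_cost
  max_dur <- params$mix$max_duration_years

  for (t in 0:(horizon - min(age0))) {
    alive <- alive & (age < horizon) # hard horizon: no accrual at age 105
    if (!any(alive)) break
    u_fr <- cbind(stream_runif(n, seed, "frac_hip", t),
                  stream_runif(n, seed, "frac_vertebral", t),
                  stream_runif(n, seed, "frac_nhnv", t))
    u_death <- stream_runif(n, seed, "death", t)
    u_nh <- stream_runif(n, seed, "nursing", t)
    u_persist <- stream_runif(n, seed, "persist", t)

    age_c <- pmin(age, horizon)          # clamp for lookups in the final cycle
    band <- findInterval(age_c, AGE_BAND_LOWER)
    band <- pmin(band, 4L)

    # effective treatment RR per site
    rr_eff <- matrix(1, n, 3)
    has_drug <- drug_id > 0L & (on_tx | stopped)
    if (any(has_drug)) {
      w <- numeric(n)
      w[on_tx] <- 1
      for (d in seq_len(ndrug)) {
        sel <- stopped & drug_id == d
        if (!any(sel)) next
        w[sel] <- switch(params$drugs[[d]]$waning,
          linear_over_treatment_duration =
            pmax(0, 1 - yrs_stop[sel] / pmax(yrs_on_at_stop[sel], 1e-12)),
          linear_over_one_year = pmax(0, 1 - yrs_stop[sel]),
          step_at_one_year = as.numeric(yrs_stop[sel] < 1))
      }
      hd <- which(has_drug)
      for (s in 1:3)
        rr_eff[hd, s] <- pmin(1, 1 - (1 - rr_drug[s, drug_id[hd]]) * w[hd])
    }

    # (1) fracture events
    msub <- subsequent_multiplier(ys_last, n_prior, sub)
    events <- matrix(FALSE, n, 3)
    for (s in 1:3) {
      base <- inc[cbind(s, band, sex_idx)]
      rr_os <- ifelse(osteo, tsr[cbind(s, band, sex_idx)], 1)
      p <- 1 - exp(-base * rr_os * msub * rr_eff[, s])
      events[, s] <- alive & (u_fr[, s] < p)
    }
    any_event <- events[, 1] | events[, 2] | events[, 3]
    worst_now <- ifelse(events[, 1], 1L,
                 ifelse(events[, 2], 2L, ifelse(events[, 3], 3L, 0L)))

    # (2) death (first-year excess for this cycle's hip/vertebral events,
    # long-term hazard-ratio excess for prior history, attribution-scaled)
    qx <- qx_tab[cbind(age_c - 49L, sex_idx)]
    excess <- ifelse(events[, 1], fy_ex[cbind(sex_idx, 1L)],
              ifelse(events[, 2], fy_ex[cbind(sex_idx, 2L)],
                     qx * (longterm_mortality_hr(ys_last_hv, mt) - 1)))
    q <- pmin(1, qx + mt$attribution * excess)
    die <- alive & (u_death < q)
    surv_credit <- ifelse(die, 0.5, 1)

    # (3) costs
    adm <- alive & events[, 1] & !in_nh &
      (u_nh < cs$nursing_home_prob_after_hip)
    in_nh <- in_nh | adm
    fr_cost <- events[, 1] * fcost[cbind(1L, sex_idx)] +
               events[, 2] * fcost[cbind(2L, sex_idx)] +
               events[, 3] * fcost[cbind(3L, sex_idx)]
    tx_cost <- numeric(n)
    ontx <- which(on_tx & alive)
    if (length(ontx) > 0) {
      d <- drug_id[ontx]
      tx_cost[ontx] <- annual_tx_cost[d] +
        ifelse(yrs_on[ontx] == 0L, ae_year1[d], ae_later[d])
    }
    cycle_cost <- fr_cost + (in_nh * nh_annual + tx_cost) * surv_credit
    df <- (1 + r)^(-(t + 0.5))
    disc_cost <- disc_cost + ifelse(alive, cycle_cost * df, 0)

    # (4) utility: most severe site only; re-fracture restarts the
    # first-year multiplier; else the worst-ever site's subsequent multiplier
    bu <- u_tab[age_c - 49L]
    um <- ifelse(any_event, fy_mult[pmax(worst_now, 1L)],
          ifelse(worst_hist > 0L, sub_mult[pmax(worst_hist, 1L)], 1))
    disc_qaly <- disc_qaly + ifelse(alive, bu * um * surv_credit * df, 0)
    life_years <- life_years + ifelse(alive, surv_credit, 0)
    frac_counts <- frac_counts + events

    # (6) advance clocks
    alive <- alive & !die
    age <- age + 1L
    ys_last <- ifelse(any_event, 1, ys_last + 1)
    hv_event <- events[, 1] | events[, 2]
    ys_last_hv <- ifelse(hv_event, 1, ys_last_hv + 1)
    n_prior <- n_prior + as.integer(rowSums(events))
    worst_hist <- ifelse(any_event & (worst_hist == 0L | worst_now < worst_hist),
                         worst_now, worst_hist)
    yrs_stop[stopped] <- yrs_stop[stopped] + 1
    sel <- which(on_tx)
    if (length(sel) > 0) {
      yrs_on[sel] <- yrs_on[sel] + 1L
      k <- yrs_on[sel]
      p_stop <- numeric(length(sel))
      for (d in seq_len(ndrug)) {
        dd <- drug_id[sel] == d
        if (any(dd)) p_stop[dd] <- discontinuation_prob(params$drugs[[d]], k[dd])
      }
      newstop <- k >= max_dur | u_persist[sel] < p_stop
      ns <- sel[newstop]
      on_tx[ns] <- FALSE
      stopped[ns] <- TRUE
      yrs_stop[ns] <- 0
      yrs_on_at_stop[ns] <- yrs_on[ns]
    }
  }

  list(disc_cost = disc_cost, disc_qaly = disc_qaly, life_years = life_years,
       fractures = frac_counts, treated = treated, upfront = upfront, n = n)
}

#' Simulate one individual's lifetime trajectory
#'
#' Applies the screening cascade at entry (screening arm only), then iterates
#' annual cycles until death or the horizon age.
#'
#' @param age,sex,osteoporotic entry characteristics.
#' @param params `osteo_params` bundle.
#' @param arm `"screening"` or `"none"`.
#' @param seed master seed.
#' @return list of lifetime accumulators: `disc_cost`, `disc_qaly`,
#'   `life_years`, `fractures` (per site).
#' @export
simulate_individual <- function(age, sex, osteoporotic, params = default_params(),
                                arm = c("screening", "none"), seed = 1) {
  roster <- data.frame(age = as.integer(age),
                       sex = factor(sex, levels = SEXES))
  res <- simulate_arm(roster, osteoporotic, params, arm, seed)
  list(disc_cost = res$disc_cost, disc_qaly = res$disc_qaly,
       life_years = res$life_years, fractures = res$fractures[1, ])
}

arm_outcome <- function(sim, cohort_id) {
  n <- sim$n
  fr_total <- rowSums(sim$fractures)
  means <- c(cost = mean(sim$disc_cost), qaly = mean(sim$disc_qaly),
             ly = mean(sim$life_years), fractures = mean(fr_total))
  ses <- c(cost = stats::sd(sim$disc_cost), qaly = stats::sd(sim$disc_qaly),
           ly = stats::sd(sim$life_years), fractures = stats::sd(fr_total)) / sqrt(n)
  out <- list(n = n, cohort_id = cohort_id, mean = means, se = ses,
              fractures_by_site = colMeans(sim$fractures),
              treated_fraction = mean(sim$treated),
              ind = list(cost = sim$disc_cost, qaly = sim$disc_qaly,
                         ly = sim$life_years, fractures = fr_total))
  class(out) <- "arm_outcome"
  out
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("arm outcome (n = %d)\n", x$n))
  cat(sprintf("  mean discounted cost : KRW %s (SE %s)\n",
              format(round(x$mean["cost"]), big.mark = ","),
              format(round(x$se["cost"]), big.mark = ",")))
  cat(sprintf("  mean discounted QALY : %.4f (SE %.4f)\n",
              x$mean["qaly"], x$se["qaly"]))
  cat(sprintf("  mean life-years      : %.4f\n", x$mean["ly"]))
  cat(sprintf("  mean fractures       : %.4f\n", x$mean["fractures"]))
  invisible(x)
}

#' Run paired screening and no-screening cohorts
#'
#' Simulates every roster member under both arms with identical
#' natural-history random streams (common random numbers), so incremental
#' differences are paired.
#'
#' @param roster data frame from [make_population()].
#' @param osteo logical vector from [assign_osteoporosis()].
#' @param params `osteo_params` bundle.
#' @param seed master seed.
#' @return list with `screening` and `no_screening` (class `arm_outcome`),
#'   sharing a cohort identity for paired incremental analysis.
#' @export
run_cohort <- function(roster, osteo, params = default_params(), seed = 1) {
  stopifnot(nrow(roster) > 0)
  cohort_id <- sprintf("n%d-seed%d", nrow(roster), child_seed(seed, "cohort"))
  scr <- simulate_arm(roster, osteo, params, "screening", seed)
  ns <- simulate_arm(roster, osteo, params, "none", seed)
  list(screening = arm_outcome(scr, cohort_id),
       no_screening = arm_outcome(ns, cohort_id))
}
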