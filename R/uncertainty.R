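# Deterministic one-way sensitivity analysis, probabilistic sensitivity
# analysis (beta / normal / log-normal families), and cost-effectiveness
# acceptability curves.

#' Packaged one-way sensitivity scenario set
#'
#' The deterministic scenario grid: DXA uptake 40-80%, treatment initiation
#' 30-70%, AI cost +/-50%, fracture incidence +/-20%, fracture costs +/-20%,
#' utility decrements +/-20%, excess mortality +/-50%, drug cost +/-20%,
#' drug efficacy +/-20% (on 1 - RR), single-drug strategies, the age >= 70
#' subgroup, and male prevalence 12.2% / 15%.
#'
#' @return list of scenarios; each has `label`, an `edit` function on the
#'   parameter bundle, and optional `sex` / `min_age` restrictions.
#' @export
default_scenarios <- function() {
  sc <- list()
  add <- function(label, edit, min_age = 50)
    sc[[length(sc) + 1L]] <<- list(label = label, edit = edit, min_age = min_age)
  for (v in c(0.4, 0.5, 0.6, 0.7, 0.8))
    add(sprintf("DXA uptake %d%%", round(100 * v)),
        local({v0 <- v; function(p) set_param(p, "cascade.p_dxa_uptake", v0)}))
  for (v in c(0.3, 0.4, 0.5, 0.6, 0.7))
    add(sprintf("Treatment initiation %d%%", round(100 * v)),
        local({v0 <- v; function(p) set_param(p, "cascade.p_treat_init", v0)}))
  for (f in c(0.5, 1.5))
    add(sprintf("AI cost %+d%%", round(100 * (f - 1))),
        local({f0 <- f; function(p) scale_param(p, "test.unit_cost", f0)}))
  for (f in c(0.8, 1.2)) {
    add(sprintf("Fracture incidence %+d%%", round(100 * (f - 1))),
        local({f0 <- f; function(p) {
          p <- scale_param(p, "incidence.female", f0)
          scale_param(p, "incidence.male", f0)
        }}))
    add(sprintf("Fracture costs %+d%%", round(100 * (f - 1))),
        local({f0 <- f; function(p)
          scale_param(p, "costs.fracture_first_year", f0)}))
    add(sprintf("Utility decrements %+d%%", round(100 * (f - 1))),
        local({f0 <- f; function(p) {
          m <- p$utility$post_fracture
          p$utility$post_fracture[] <- pmin(1, pmax(0.01, 1 - (1 - m) * f0))
          p
        }}))
    add(sprintf("Drug costs %+d%%", round(100 * (f - 1))),
        local({f0 <- f; function(p) {
          p <- scale_param(p, "drugs.alendronate.annual_cost", f0)
          scale_param(p, "drugs.denosumab.annual_cost", f0)
        }}))
    add(sprintf("Drug efficacy %+d%%", round(100 * (f - 1))),
        local({f0 <- f; function(p) {
          for (d in names(p$drugs))
            p$drugs[[d]]$rr <- pmin(pmax(1 - (1 - p$drugs[[d]]$rr) * f0, 0.01), 1)
          p
        }}))
  }
  for (f in c(0.5, 1.5))
    add(sprintf("Excess mortality %+d%%", round(100 * (f - 1))),
        local({f0 <- f; function(p) {
          p$mortality$first_year_excess <-
            pmin(1, p$mortality$first_year_excess * f0)
          p$mortality$longterm_hr0 <- 1 + (p$mortality$longterm_hr0 - 1) * f0
          p
        }}))
  add("Alendronate only", function(p)
    set_param(p, "mix.shares", c(alendronate = 1, denosumab = 0)))
  add("Denosumab only", function(p)
    set_param(p, "mix.shares", c(alendronate = 0, denosumab = 1)))
  add("Age >= 70", function(p) p, min_age = 70)
  for (v in c(0.122, 0.15))
    add(sprintf("Male prevalence %.1f%%", 100 * v),
        local({v0 <- v; function(p) {
          p$prevalence$fixed[["male"]] <- v0
          p
        }}))
  sc
}

#' One-way deterministic sensitivity analysis
#'
#' Runs every scenario with the same seed (hence, where the subgroup is
#' unchanged, the same roster and paired random streams) as the base case.
#'
#' @param params base-case `osteo_params` bundle.
#' @param scenarios scenario list as from [default_scenarios()].
#' @param n cohort size per scenario.
#' @param seed master seed shared across scenarios.
#' @return data frame (class `osteo_dsa`) with one row per scenario plus the
#'   base case: `label`, `delta_cost`, `delta_qaly`, `icer`, `label_icer`,
#'   and `icer_deviation` from base (tornado ordering key).
#' @export
one_way_table <- function(params = default_params(),
                          scenarios = default_scenarios(),
                          n = 10000, seed = 1) {
  run1 <- function(p, min_age) {
    res <- run_model(p, n = n, seed = seed, min_age = min_age)
    c(dc = res$incremental$delta_cost, dq = res$incremental$delta_qaly,
      icer = res$incremental$icer)
  }
  base <- run1(params, 50)
  rows <- lapply(scenarios, function(sc) {
    v <- run1(sc$edit(params), sc$min_age)
    data.frame(label = sc$label, delta_cost = v[["dc"]],
               delta_qaly = v[["dq"]], icer = v[["icer"]])
  })
  out <- rbind(data.frame(label = "Base case", delta_cost = base[["dc"]],
                          delta_qaly = base[["dq"]], icer = base[["icer"]]),
               do.call(rbind, rows))
  out$icer_deviation <- abs(out$icer - base[["icer"]])
  rownames(out) <- NULL
  class(out) <- c("osteo_dsa", "data.frame")
  attr(out, "base_icer") <- base[["icer"]]
  out
}

#' Evaluate the DXA-uptake and treatment-initiation grids exactly
#'
#' Incremental results along the cascade follow-up grids (DXA uptake,
#' treatment initiation).  Because every random stream is a labelled child of
#' the master seed, the simulated outcome at any `(p_dxa_uptake,
#' p_treat_init)` pair is an exact deterministic function of two boundary
#' simulations: the no-screening arm, and the screening arm run at the
#' largest grid probabilities (treated sets are nested as the probabilities
#' rise, and a person's trajectory given their treatment status does not
#' depend on the cascade probabilities).  This lets the whole grid be
#' evaluated from one paired run at full common-random-number reuse, with no
#' extra Monte-Carlo noise between grid points: the result per point is
#' identical to calling [run_model()] with that configuration and the same
#' seed.
#'
#' @param params base `osteo_params` bundle.
#' @param n cohort size.
#' @param seed master seed.
#' @param dxa_grid DXA-uptake values (evaluated at the base initiation rate).
#' @param init_grid initiation values (evaluated at the base DXA uptake).
#' @return data frame with `parameter`, `value`, `delta_cost`, `delta_qaly`,
#'   `icer`.
#' @export
cascade_grid <- function(params = default_params(), n = 10000, seed = 1,
                         dxa_grid = c(0.4, 0.5, 0.6, 0.7, 0.8),
                         init_grid = c(0.3, 0.4, 0.5, 0.6, 0.7)) {
  base_dxa <- params$cascade$p_dxa_uptake
  base_init <- params$cascade$p_treat_init
  sup <- params
  sup$cascade$p_dxa_uptake <- max(dxa_grid, base_dxa)
  sup$cascade$p_treat_init <- max(init_grid, base_init)

  roster <- make_population(n, params$population, seed)
  osteo <- assign_osteoporosis(roster, params$prevalence, seed)
  none <- simulate_arm(roster, osteo, params, "none", seed)
  scr <- simulate_arm(roster, osteo, sup, "screening", seed)

  te <- params$test
  u_flag <- stream_runif(n, seed, "cascade_flag")
  u_dxa <- stream_runif(n, seed, "cascade_dxa")
  u_init <- stream_runif(n, seed, "cascade_init")
  flagged <- u_flag < ifelse(osteo, te$sensitivity, 1 - te$specificity)
  core_cost <- scr$disc_cost - scr$upfront

  eval_point <- function(p_dxa, p_init) {
    dxa_done <- flagged & (u_dxa < p_dxa)
    treated <- dxa_done & osteo & (u_init < p_init)
    cost <- te$unit_cost + ifelse(dxa_done, params$cascade$dxa_cost, 0) +
      ifelse(treated, core_cost, none$disc_cost)
    dq <- mean(ifelse(treated, scr$disc_qaly, none$disc_qaly) - none$disc_qaly)
    dc <- mean(cost - none$disc_cost)
    c(delta_cost = dc, delta_qaly = dq,
      icer = classify_icer(dc, dq)$icer)
  }
  rows <- rbind(
    t(vapply(dxa_grid, function(v) eval_point(v, base_init), numeric(3))),
    t(vapply(init_grid, function(v) eval_point(base_dxa, v), numeric(3))))
  data.frame(parameter = rep(c("p_dxa_uptake", "p_treat_init"),
                             c(length(dxa_grid), length(init_grid))),
             value = c(dxa_grid, init_grid), rows)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Samples parameters from the assigned families, moment-matched to the base
#' values: beta for fracture incidence (on the annual-rate scale) and
#' post-fracture utility multipliers (CI-matched where 95% CIs are packaged,
#' otherwise coefficient of variation `cv`); normal truncated at 0 for all
#' unit costs; log-normal (median = base, `cv`) for treatment relative
#' risks, capped at 1.  Cascade probabilities are kept at base-case values
#' unless `include_cascade = TRUE` (beta, `cv`).  `cv = 0` returns the base
#' bundle unchanged.
#'
#' @param base base-case `osteo_params` bundle.
#' @param seed seed for this draw.
#' @param cv default coefficient of variation (0.10).
#' @param include_cascade also redraw DXA-uptake and initiation
#'   probabilities.
#' @return a perturbed `osteo_params` bundle.
#' @export
draw_psa_params <- function(base, seed = 1, cv = 0.10, include_cascade = FALSE) {
  stopifnot(cv >= 0)
  if (cv == 0) return(base)
  set.seed(child_seed(seed, "psa_draw"))
  p <- base

  rbeta_m <- function(mean, se) {
    if (mean <= 0) return(mean)
    se <- min(se, 0.99 * sqrt(mean * (1 - mean)))
    nu <- mean * (1 - mean) / se^2 - 1
    if (nu <= 0) stop("beta moment matching failed: se too large for mean ", mean)
    stats::rbeta(1, mean * nu, (1 - mean) * nu)
  }
  rnorm_pos <- function(mean, se) max(0, stats::rnorm(1, mean, se))
  rlnorm_med <- function(med, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    min(1, stats::rlnorm(1, log(med), sdlog))
  }

  for (sx in SEXES) {
    m <- p$incidence[[sx]]
    m[] <- vapply(as.numeric(m), function(x) rbeta_m(x, cv * x), numeric(1))
    p$incidence[[sx]] <- m
  }
  ci <- base$utility$post_fracture_ci
  for (ph in c("first_year", "subsequent")) {
    for (s in SITES) {
      m0 <- base$utility$post_fracture[s, ph]
      se <- (ci[[ph]][s, "hi"] - ci[[ph]][s, "lo"]) / (2 * stats::qnorm(0.975))
      p$utility$post_fracture[s, ph] <- rbeta_m(min(m0, 0.999), se)
    }
  }
  for (s in SITES) for (sx in SEXES) {
    m0 <- base$costs$fracture_first_year[s, sx]
    p$costs$fracture_first_year[s, sx] <- rnorm_pos(m0, cv * m0)
  }
  for (f in c("nursing_home_daily_cost", "physician_visit_cost",
              "pharmacy_visit_cost", "dxa_cost"))
    p$costs[[f]] <- rnorm_pos(base$costs[[f]], cv * base$costs[[f]])
  p$test$unit_cost <- rnorm_pos(base$test$unit_cost, cv * base$test$unit_cost)
  p$cascade$dxa_cost <- p$costs$dxa_cost
  for (d in names(p$drugs)) {
    p$drugs[[d]]$annual_cost <-
      rnorm_pos(base$drugs[[d]]$annual_cost, cv * base$drugs[[d]]$annual_cost)
    rr <- base$drugs[[d]]$rr
    p$drugs[[d]]$rr <- stats::setNames(
      vapply(rr, function(x) rlnorm_med(x, cv), numeric(1)), names(rr))
  }
  if (include_cascade) {
    p$cascade$p_dxa_uptake <-
      rbeta_m(base$cascade$p_dxa_uptake, cv * base$cascade$p_dxa_uptake)
    p$cascade$p_treat_init <-
      rbeta_m(base$cascade$p_treat_init, cv * base$cascade$p_treat_init)
  }
  p
}

#' Probabilistic sensitivity analysis
#'
#' For each outer draw, samples a parameter set with [draw_psa_params()] and
#' runs paired inner cohorts, recording the incremental cost and QALY pair.
#' The roster and osteoporosis flags are held fixed across draws (parameter
#' uncertainty only); inner Monte-Carlo streams differ per draw.
#'
#' @param base base-case `osteo_params` bundle.
#' @param n_outer number of outer parameter draws (default 200).
#' @param n_inner inner cohort size per draw (default 10,000; the source
#'   scale of 250,000 trials is available by setting it here).
#' @param seed master seed.
#' @param cv default dispersion passed to [draw_psa_params()].
#' @param include_cascade passed to [draw_psa_params()].
#' @return data frame (class `osteo_psa`) with columns `draw`, `delta_cost`,
#'   `delta_qaly`.
#' @export
run_psa <- function(base = default_params(), n_outer = 200, n_inner = 10000,
                    seed = 1, cv = 0.10, include_cascade = FALSE) {
  stopifnot(n_outer >= 1)
  roster <- make_population(n_inner, base$population, child_seed(seed, "psa_roster"))
  osteo <- assign_osteoporosis(roster, base$prevalence, child_seed(seed, "psa_roster"))
  res <- matrix(NA_real_, n_outer, 2)
  for (j in seq_len(n_outer)) {
    pj <- draw_psa_params(base, child_seed(seed, "psa_outer", j), cv,
                          include_cascade)
    arms <- run_cohort(roster, osteo, pj, child_seed(seed, "psa_inner", j))
    inc <- incremental(arms$screening, arms$no_screening)
    res[j, ] <- c(inc$delta_cost, inc$delta_qaly)
  }
  out <- data.frame(draw = seq_len(n_outer), delta_cost = res[, 1],
                    delta_qaly = res[, 2])
  class(out) <- c("osteo_psa", "data.frame")
  attr(out, "n_inner") <- n_inner
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA samples with non-negative net monetary benefit at each
#' willingness-to-pay threshold (ties count as cost-effective).
#'
#' @param samples an `osteo_psa` data frame (or any data frame with
#'   `delta_cost` and `delta_qaly`).
#' @param wtp_grid thresholds in KRW/QALY (default 0 to 6e7 in 2e6 steps).
#' @return data frame with `wtp` and `probability`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 6e7, by = 2e6)) {
  stopifnot(nrow(samples) > 0)
  prob <- vapply(wtp_grid, function(w)
    mean(w * samples$delta_qaly - samples$delta_cost >= 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' @export
print.osteo_psa <- function(x, ...) {
  cat(sprintf("PSA: %d outer draws, inner cohorts of %s\n", nrow(x),
              format(attr(x, "n_inner"), big.mark = ",")))
  cat(sprintf("  mean delta cost: KRW %s; mean delta QALY: %.5f\n",
              format(round(mean(x$delta_cost)), big.mark = ","),
              mean(x$delta_qaly)))
  cc <- ceac(x, 3e7)
  cat(sprintf("  P(cost-effective at KRW 30M/QALY) = %.1f%%\n",
              100 * cc$probability))
  invisible(x)
}

#' Plot the cost-effectiveness acceptability curve of a PSA
#'
#' @param x an `osteo_psa` object.
#' @param wtp_grid thresholds passed to [ceac()].
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.osteo_psa <- function(x, wtp_grid = seq(0, 6e7, by = 2e6), ...) {
  cc <- ceac(x, wtp_grid)
  graphics::plot(cc$wtp / 1e6, cc$probability, type = "b", pch = 16,
                 xlab = "Willingness to pay (million KRW per QALY)",
                 ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::abline(v = 30, lty = 2, col = "grey40")
  invisible(cc)
}
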