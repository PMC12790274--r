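#' Convert an event rate to a per-cycle probability
#'
#' Constant-hazard conversion `1 - exp(-rate * dt)`, used to turn annual
#' fracture incidence rates and mortality hazards into cycle probabilities.
#'
#' @param rate non-negative event rate (events per person-year); vectorised.
#' @param dt cycle length in years (default 1).
#' @return probability in `[0, 1)`.
#' @examples
#' rate_to_prob(0.0136)           # 0.013508
#' @export
rate_to_prob <- function(rate, dt = 1) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(dt <= 0)) stop("dt must be positive")
  1 - exp(-rate * dt)
}

#' Baseline (pre-fracture) utility at a given age
#'
#' Linear interpolation between the packaged utility knots (ages 50 to 90 in
#' 5-year steps); above the last knot the value is held constant.
#'
#' @param age age in years, `>= 50`; vectorised.
#' @param utility utility parameter block (`params$utility`).
#' @return utility value(s) in `[0, 1]`.
#' @export
baseline_utility <- function(age, utility = default_params()$utility) {
  if (any(age < 50)) stop("age must be >= 50")
  stats::approx(utility$baseline_ages, utility$baseline, xout = age,
                rule = 2)$y
}

#' Discount factor at a given time from model entry
#'
#' @param years_from_start non-negative time in years; vectorised.
#' @param discount_rate annual discount rate (default 0.045).
#' @return `(1 + discount_rate)^(-years_from_start)`.
#' @export
discount_factor <- function(years_from_start, discount_rate = 0.045) {
  if (any(years_from_start < 0)) stop("years_from_start must be non-negative")
  (1 + discount_rate)^(-years_from_start)
}

# 10-year age band index (1..4) for incidence / T-score RR lookup.
# Bands are half-open [50,60), [60,70), [70,80), [80,105).
age_band_index <- function(age) {
  if (any(age < 50 | age >= 105)) stop("age outside the modelled range [50, 105)")
  findInterval(age, AGE_BAND_LOWER)
}

# prevalence band index (1..3) for the age-specific scenario: 50-59/60-69/70+
prevalence_band_index <- function(age) {
  if (any(age < 50)) stop("age must be >= 50")
  pmin(findInterval(age, c(50, 60, 70)), 3L)
}

#' Subsequent-fracture risk multiplier
#'
#' Relative risk of a new fracture given fracture history, as a function of
#' years since the most recent fracture and the number of prior fractures.
#' The packaged default (a synthetic stand-in) is piecewise in time
#' (2.0 within 2 years, 1.5 for years 3-5, 1.2 beyond) plus 0.2 per prior
#' fracture beyond the first, capped at 4.0.
#'
#' @param years_since years since the last fracture (Inf if none); vectorised.
#' @param n_prior number of prior fractures; vectorised.
#' @param model multiplier model (`params$subsequent`).
#' @return relative risk `>= 1`.
#' @export
subsequent_multiplier <- function(years_since, n_prior,
                                  model = default_subsequent_multipliers()) {
  k <- max(length(years_since), length(n_prior))
  ys <- rep_len(years_since, k)
  np <- rep_len(n_prior, k)
  base <- ifelse(ys <= model$recent_years, model$recent,
                 ifelse(ys <= model$mid_years, model$mid, model$late))
  out <- pmin(base + model$per_extra_prior * pmax(0, np - 1), model$cap)
  out[np == 0] <- 1
  out
}

# long-term post-fracture mortality hazard ratio on qx (before attribution
# scaling); declines linearly from hr0 toward 1 over decay_years
longterm_mortality_hr <- function(years_since, mortality) {
  w <- pmax(0, 1 - years_since / mortality$longterm_decay_years)
  w[!is.finite(years_since)] <- 0
  1 + (mortality$longterm_hr0 - 1) * w
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the model inputs (probabilities in
#' range, non-negative costs, persistence non-increasing, treatment shares
#' summing to 1, full incidence coverage, monotone life table, ...).
#' Violations are returned as data, not raised.
#'
#' @param params an `osteo_params` object.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_params <- function(params) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)
  in01 <- function(x) all(x >= 0 & x <= 1)

  with(params$test, {
    if (!in01(c(sensitivity, specificity))) bad("test: sensitivity/specificity outside [0,1]")
    if (unit_cost < 0) bad("test: unit_cost negative")
  })
  with(params$cascade, {
    if (!in01(c(p_dxa_uptake, p_treat_init))) bad("cascade: probabilities outside [0,1]")
    if (dxa_cost < 0) bad("cascade: dxa_cost negative")
  })
  for (sx in SEXES) {
    inc <- params$incidence[[sx]]
    if (!identical(dim(inc), c(3L, 4L)) || any(inc < 0))
      bad(sprintf("incidence (%s): must be a non-negative 3x4 site-by-band table", sx))
    else for (s in c("hip", "vertebral"))
      if (is.unsorted(inc[s, ])) bad(sprintf(
        "incidence (%s, %s): not non-decreasing with age", sx, s))
    rr <- params$tscore_rr[[sx]]
    if (!identical(dim(rr), c(3L, 4L)) || any(rr < 1))
      bad(sprintf("tscore_rr (%s): all relative risks must be >= 1", sx))
    qx <- params$life_table[[sx]]
    if (!in01(qx)) bad(sprintf("life_table (%s): qx outside [0,1]", sx))
    if (qx[length(qx)] != 1) bad(sprintf("life_table (%s): qx at horizon must be 1", sx))
    if (is.unsorted(qx[seq_len(length(qx) - 1L)]))
      bad(sprintf("life_table (%s): qx not non-decreasing", sx))
  }
  sub <- params$subsequent
  if (subsequent_multiplier(1, 0, sub) != 1) bad("subsequent: multiplier(.,0) must be 1")
  grid <- expand.grid(t = c(0, 1, 3, 6, 20), k = 1:6)
  m <- subsequent_multiplier(grid$t, grid$k, sub)
  if (any(m < 1)) bad("subsequent: multiplier must be >= 1")
  for (k in 1:6) {
    mk <- subsequent_multiplier(c(0, 1, 3, 6, 20), k, sub)
    if (is.unsorted(rev(mk))) bad("subsequent: multiplier must be non-increasing in years since")
  }
  if (is.unsorted(subsequent_multiplier(1, 1:6, sub)))
    bad("subsequent: multiplier must be non-decreasing in prior fractures")

  mt <- params$mortality
  if (!in01(mt$attribution)) bad("mortality: attribution outside [0,1]")
  if (any(mt$first_year_excess < 0) || !in01(mt$first_year_excess))
    bad("mortality: first_year_excess outside [0,1]")
  if (mt$longterm_hr0 < 1) bad("mortality: longterm_hr0 must be >= 1")

  for (d in names(params$drugs)) {
    dr <- params$drugs[[d]]
    if (!identical(sort(names(dr$rr)), sort(SITES)))
      bad(sprintf("drugs (%s): rr must be named by site (hip, vertebral, nhnv)", d))
    if (any(dr$rr <= 0 | dr$rr > 1)) bad(sprintf("drugs (%s): rr outside (0,1]", d))
    if (!in01(dr$persistence)) bad(sprintf("drugs (%s): persistence outside [0,1]", d))
    if (is.unsorted(rev(dr$persistence)))
      bad(sprintf("drugs (%s): persistence non-increasing violated", d))
    if (dr$annual_cost < 0) bad(sprintf("drugs (%s): annual_cost negative", d))
    if (any(unlist(dr$monitoring) < 0) || any(unlist(dr$ae) < 0))
      bad(sprintf("drugs (%s): monitoring/AE quantities must be >= 0", d))
    if (!dr$waning %in% c("linear_over_treatment_duration", "linear_over_one_year",
                          "step_at_one_year"))
      bad(sprintf("drugs (%s): unknown waning rule '%s'", d, dr$waning))
  }
  if (abs(sum(params$mix$shares) - 1) > 1e-8) bad("mix: shares must sum to 1")
  if (!all(names(params$mix$shares) %in% names(params$drugs)))
    bad("mix: share names must match drug names")
  if (params$mix$max_duration_years < 1) bad("mix: max_duration_years must be >= 1")

  cs <- params$costs
  if (any(cs$fracture_first_year < 0)) bad("costs: fracture costs must be >= 0")
  if (!in01(cs$nursing_home_prob_after_hip)) bad("costs: nursing_home_prob_after_hip outside [0,1]")
  if (any(c(cs$nursing_home_daily_cost, cs$physician_visit_cost,
            cs$pharmacy_visit_cost, cs$dxa_cost) < 0))
    bad("costs: unit costs must be >= 0")

  ut <- params$utility
  if (!in01(ut$baseline)) bad("utility: baseline outside [0,1]")
  if (length(ut$baseline) != length(ut$baseline_ages))
    bad("utility: baseline knots and ages differ in length")
  if (any(ut$post_fracture <= 0 | ut$post_fracture > 1.1))
    bad("utility: post-fracture multipliers outside (0, 1.1]")

  pv <- params$prevalence
  if (!pv$mode %in% c("fixed", "age_specific")) bad("prevalence: unknown mode")
  if (!in01(pv$fixed) || !in01(pv$age_specific)) bad("prevalence: proportions outside [0,1]")

  pop <- params$population
  if (any(pop$age_weights < 0)) bad("population: age weights must be >= 0")
  if (sum(pop$age_weights) <= 0) bad("population: age weights must not all be zero")
  if (abs(sum(pop$sex_shares) - 1) > 1e-8) bad("population: sex shares must sum to 1")

  ec <- params$econ
  if (ec$discount_rate < 0) bad("econ: discount_rate must be >= 0")
  if (ec$horizon_age <= 50) bad("econ: horizon_age must exceed 50")
  if (ec$cycle_length != 1) bad("econ: only annual cycles are supported")
  v
}

# ---- configuration loading --------------------------------------------------

# recursively merge a user config into the defaults; unknown keys are an error
merge_config <- function(base, cfg, path = character(0)) {
  if (!is.list(cfg)) stop("config section '", paste(path, collapse = "."),
                          "' must be a mapping")
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown, sep = "", collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(base[[k]]) && !is.list(cfg[[k]]) && !is.null(names(base[[k]])))
      stop("config key '", paste(c(path, k), collapse = "."), "' must be a mapping")
    if (is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], as.list(cfg[[k]]), c(path, k))
    } else {
      base[[k]] <- coerce_leaf(base[[k]], cfg[[k]], c(path, k))
    }
  }
  base
}

# coerce a config leaf onto the shape of the default leaf (scalar, named
# vector, or matrix given row-wise as a named list)
coerce_leaf <- function(default, value, path) {
  lab <- paste(path, collapse = ".")
  if (is.matrix(default)) {
    if (is.list(value) && is.null(names(value))) { # row-wise array (JSON dump)
      m <- do.call(rbind, lapply(value, function(r) as.numeric(unlist(r))))
      if (!all(dim(m) == dim(default))) stop("wrong shape for ", lab)
      default[] <- m
      return(default)
    }
    if (is.list(value)) {
      for (rn in names(value)) {
        if (!rn %in% rownames(default)) stop("unknown row '", rn, "' in ", lab)
        default[rn, ] <- as.numeric(unlist(value[[rn]]))
      }
      return(default)
    }
    value <- as.numeric(unlist(value))
    if (length(value) != length(default)) stop("wrong length for ", lab)
    default[] <- value
    return(default)
  }
  if (is.numeric(default)) {
    out <- as.numeric(unlist(value))
    if (length(default) > 1L && length(out) != length(default))
      stop("wrong length for ", lab)
    names(out) <- names(default)[seq_along(out)]
    return(out)
  }
  if (is.character(default)) return(as.character(value))
  if (is.logical(default)) return(as.logical(value))
  value
}

# set a single parameter by dot-separated path, e.g. "cascade.p_dxa_uptake"
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (i in seq_along(keys)) {
    if (!keys[i] %in% names(node)) stop("unknown parameter path: ", path)
    if (i < length(keys)) node <- node[[keys[i]]]
  }
  expr <- paste0("params", paste0("[['", keys, "']]", collapse = ""))
  leaf <- eval(parse(text = expr))
  value <- coerce_leaf(leaf, value, keys)
  eval(parse(text = paste0(expr, " <- value")))
  params
}

# multiply a numeric parameter (scalar, vector or matrix) by a factor
scale_param <- function(params, path, factor) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- paste0("params", paste0("[['", keys, "']]", collapse = ""))
  leaf <- eval(parse(text = expr))
  if (is.null(leaf)) stop("unknown parameter path: ", path)
  leaf <- leaf * factor
  eval(parse(text = paste0(expr, " <- leaf")))
  params
}

#' Load model parameters from a configuration file
#'
#' Reads a JSON or YAML file whose (possibly partial) structure mirrors
#' [default_params()]; unspecified fields keep their packaged base-case
#' values.  Unknown keys are rejected.  `overrides` are applied last, as
#' dot-separated paths (e.g. `list("cascade.p_dxa_uptake" = 0.8)`).
#'
#' @param path path to a `.json`, `.yaml`/`.yml` config file, or `NULL` for
#'   the packaged base case.
#' @param overrides named list of dot-path overrides applied after the file.
#' @return a validated `osteo_params` object.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  params <- default_params()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                         simplifyDataFrame = FALSE)
    } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else stop("config must be .json, .yaml or .yml: ", path)
    # regenerate the life table if Gompertz-Makeham inputs were changed
    params <- merge_config(params, cfg)
    if (!is.null(cfg$gompertz)) {
      for (sx in SEXES)
        params$life_table[[sx]] <- make_life_table(
          sx, params$gompertz[[sx]], horizon_age = params$econ$horizon_age)
    }
  }
  for (k in names(overrides)) params <- set_param(params, k, overrides[[k]])
  class(params) <- "osteo_params"
  viol <- validate_params(params)
  if (length(viol) > 0)
    stop("invalid configuration:\n", paste(" -", viol, collapse = "\n"))
  params
}
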