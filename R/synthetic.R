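# Synthetic stand-ins for model inputs that the national data sources do not
# publish in reusable form: life tables, population age/sex structure,
# post-fracture excess mortality and subsequent-fracture multipliers.  Every
# generated object carries `source = "synthetic stand-in"` so that run
# manifests can report exactly which inputs were substituted.

#' Build a synthetic life table from Gompertz-Makeham parameters
#'
#' Annual death probabilities `qx` for integer ages 50..`horizon_age`, from a
#' Gompertz-Makeham hazard
#' `makeham + gompertz_scale * exp(gompertz_shape * (age - reference_age))`
#' converted with [rate_to_prob()].  `qx` is forced to 1 at the horizon age.
#' The packaged sex-specific defaults are calibrated so that life expectancy
#' at age 50 is about 36 years (women) and 31 years (men).
#'
#' @param sex `"female"` or `"male"` (label only).
#' @param gm list with `makeham`, `gompertz_scale`, `gompertz_shape`,
#'   `reference_age`.
#' @param horizon_age terminal age (default 105).
#' @return named numeric vector of `qx`, names = ages, with attribute
#'   `source = "synthetic stand-in"`.
#' @export
make_life_table <- function(sex = c("female", "male"), gm, horizon_age = 105) {
  sex <- match.arg(sex)
  stopifnot(gm$makeham >= 0, gm$gompertz_scale >= 0, gm$gompertz_shape >= 0)
  ages <- 50:horizon_age
  hazard <- gm$makeham + gm$gompertz_scale *
    exp(gm$gompertz_shape * (ages - gm$reference_age))
  qx <- rate_to_prob(hazard, 1)
  qx[length(qx)] <- 1
  names(qx) <- ages
  attr(qx, "source") <- "synthetic stand-in"
  qx
}

#' Life expectancy from a life table
#'
#' Direct life-table summation with mid-year credit in the year of death.
#'
#' @param qx named vector of annual death probabilities (names = ages).
#' @param from_age age at which to evaluate remaining life expectancy.
#' @return expected remaining years of life.
#' @export
life_expectancy <- function(qx, from_age = 50) {
  ages <- as.integer(names(qx))
  keep <- ages >= from_age
  q <- qx[keep]
  S <- cumprod(1 - q)
  Sprev <- c(1, S[-length(S)])
  sum(S + 0.5 * (Sprev - S))
}

#' Generate a synthetic population roster
#'
#' Samples `n` individuals by sex and 5-year age band, with uniform integer
#' ages within each band.  The packaged default weights skew toward ages
#' 50-69, emulating an aging-society 50+ population.
#'
#' @param n number of individuals.
#' @param population population block (`params$population`).
#' @param seed master seed; sampling uses the `"population"` child stream.
#' @param min_age drop age bands entirely below this age (subgroup analyses).
#' @return data frame with columns `age` (integer) and `sex` (factor
#'   female/male).
#' @export
make_population <- function(n, population = default_params()$population,
                            seed = 1, min_age = 50) {
  stopifnot(n >= 0)
  w <- population$age_weights
  lower <- population$age_band_lower
  w[lower + 5 <= min_age] <- 0
  if (sum(w) <= 0) stop("population age weights are all zero")
  if (n == 0)
    return(data.frame(age = integer(0),
                      sex = factor(character(0), levels = SEXES)))
  set.seed(child_seed(seed, "population"))
  band <- sample.int(length(w), n, replace = TRUE, prob = w)
  age <- lower[band] + sample.int(5L, n, replace = TRUE) - 1L
  age <- pmax(age, as.integer(min_age))
  sex <- factor(ifelse(stats::runif(n) < population$sex_shares[["female"]],
                       "female", "male"), levels = SEXES)
  data.frame(age = age, sex = sex)
}

#' Assign osteoporosis status to a roster
#'
#' Bernoulli draws per person with the fixed (37.3% women / 7.5% men) or
#' age-band-specific prevalence, per `prevalence$mode`.
#'
#' @param roster data frame from [make_population()].
#' @param prevalence prevalence block (`params$prevalence`).
#' @param seed master seed; uses the `"osteoporosis"` child stream.
#' @return logical vector, `TRUE` = osteoporotic (BMD T-score <= -2.5).
#' @export
assign_osteoporosis <- function(roster, prevalence = default_params()$prevalence,
                                seed = 1) {
  n <- nrow(roster)
  if (n == 0) return(logical(0))
  p <- if (prevalence$mode == "fixed") {
    unname(prevalence$fixed[as.character(roster$sex)])
  } else {
    band <- prevalence_band_index(roster$age)
    prevalence$age_specific[cbind(match(as.character(roster$sex), SEXES), band)]
  }
  stream_runif(n, seed, "osteoporosis") < p
}

#' Default post-fracture mortality stand-in
#'
#' First-year excess death probability after hip (0.15 men / 0.10 women) and
#' vertebral (0.06 / 0.04) fractures, a long-term hazard ratio on baseline
#' mortality declining from 1.8 to 1.0 over 10 years, and an attribution
#' fraction of 0.25 (only a quarter of post-fracture excess mortality is
#' causally credited to the fracture).  NHNV fractures carry no excess.
#' All magnitudes except the attribution fraction are synthetic stand-ins.
#'
#' @return list with `first_year_excess` (sex-by-site matrix),
#'   `longterm_hr0`, `longterm_decay_years`, `attribution`, `source`.
#' @export
default_post_fracture_mortality <- function() {
  list(
    first_year_excess = cbind(hip = c(female = 0.10, male = 0.15),
                              vertebral = c(female = 0.04, male = 0.06)),
    longterm_hr0 = 1.8,
    longterm_decay_years = 10,
    attribution = 0.25,
    source = "synthetic stand-in"
  )
}

#' Default subsequent-fracture multiplier stand-in
#'
#' Piecewise relative risk by time since the last fracture (2.0 within
#' 2 years, 1.5 for years 3-5, 1.2 beyond), plus 0.2 per prior fracture
#' beyond the first, capped at 4.0.  Evaluate with
#' [subsequent_multiplier()].
#'
#' @return list of multiplier model settings with `source` metadata.
#' @export
default_subsequent_multipliers <- function() {
  list(recent = 2.0, mid = 1.5, late = 1.2,
       recent_years = 2, mid_years = 5,
       per_extra_prior = 0.2, cap = 4.0,
       source = "synthetic stand-in")
}
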