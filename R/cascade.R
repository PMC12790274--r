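# Decision-tree screening cascade: AI chest-radiograph flag -> DXA
# confirmation -> treatment initiation.  DXA is treated as a perfect
# reference (the confirmatory gold standard), so false-positive AI flags
# incur DXA cost but are never treated.  The AI read cost is charged to every
# screened person: the radiograph itself already exists (opportunistic), only
# its AI analysis is paid for.

#' Simulate the screening cascade for a cohort
#'
#' Per person: flag ~ Bernoulli(sensitivity) if osteoporotic, else
#' Bernoulli(1 - specificity); DXA uptake ~ Bernoulli(p_dxa_uptake) given a
#' flag; confirmation = true status (perfect-reference DXA); treatment
#' initiation ~ Bernoulli(p_treat_init) given confirmation; drug sampled from
#' the treatment mix and fixed thereafter.
#'
#' @param has_osteoporosis logical vector of true disease status.
#' @param params `osteo_params` bundle (uses `test`, `cascade`, `mix`).
#' @param seed master seed; uses the `"cascade_*"` child streams.
#' @return data frame with columns `flagged`, `dxa_done`, `confirmed`,
#'   `treated`, `drug` (factor, `NA` if untreated), `upfront_cost` (KRW).
#' @export
screen_cohort <- function(has_osteoporosis, params = default_params(), seed = 1) {
  n <- length(has_osteoporosis)
  te <- params$test; ca <- params$cascade
  u_flag <- stream_runif(n, seed, "cascade_flag")
  u_dxa <- stream_runif(n, seed, "cascade_dxa")
  u_init <- stream_runif(n, seed, "cascade_init")
  u_drug <- stream_runif(n, seed, "cascade_drug")
  p_flag <- ifelse(has_osteoporosis, te$sensitivity, 1 - te$specificity)
  flagged <- u_flag < p_flag
  dxa_done <- flagged & (u_dxa < ca$p_dxa_uptake)
  confirmed <- dxa_done & has_osteoporosis
  treated <- confirmed & (u_init < ca$p_treat_init)
  shares <- params$mix$shares
  drug_idx <- findInterval(u_drug, cumsum(shares), left.open = TRUE) + 1L
  drug <- factor(ifelse(treated, names(shares)[drug_idx], NA),
                 levels = names(params$drugs))
  data.frame(flagged = flagged, dxa_done = dxa_done, confirmed = confirmed,
             treated = treated, drug = drug,
             upfront_cost = te$unit_cost + ifelse(dxa_done, ca$dxa_cost, 0))
}

#' Simulate one individual's screening pathway
#'
#' @inheritParams screen_cohort
#' @param has_osteoporosis logical scalar.
#' @return one-row data frame as in [screen_cohort()].
#' @export
screen_individual <- function(has_osteoporosis, params = default_params(),
                              seed = 1) {
  stopifnot(length(has_osteoporosis) == 1L)
  screen_cohort(has_osteoporosis, params, seed)
}

#' Closed-form pathway probabilities of the screening cascade
#'
#' Analytic expected values of the decision tree, used as the oracle against
#' which Monte-Carlo cascade frequencies are checked:
#' `P(flag) = prev * sens + (1 - prev) * (1 - spec)`,
#' `P(dxa) = P(flag) * p_dxa_uptake`,
#' `P(confirmed) = prev * sens * p_dxa_uptake`,
#' `P(treated) = P(confirmed) * p_treat_init`,
#' `E[upfront cost] = ai_cost + P(dxa) * dxa_cost`.
#'
#' @param prevalence disease prevalence among the screened, in `[0,1]`.
#' @param params `osteo_params` bundle.
#' @return named list of pathway probabilities and expected upfront cost.
#' @export
expected_cascade <- function(prevalence, params = default_params()) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  te <- params$test; ca <- params$cascade
  p_flag <- prevalence * te$sensitivity + (1 - prevalence) * (1 - te$specificity)
  p_dxa <- p_flag * ca$p_dxa_uptake
  p_confirmed <- prevalence * te$sensitivity * ca$p_dxa_uptake
  p_treated <- p_confirmed * ca$p_treat_init
  list(p_flag = p_flag, p_dxa = p_dxa, p_confirmed = p_confirmed,
       p_treated = p_treated,
       expected_upfront_cost = te$unit_cost + p_dxa * ca$dxa_cost)
}
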