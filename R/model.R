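#' Run the full cost-effectiveness analysis
#'
#' One call generates a synthetic population roster, assigns osteoporosis
#' status, simulates the paired screening and no-screening arms, and returns
#' incremental results: the base-case deterministic analysis of the model.
#'
#' @param params `osteo_params` bundle (see [default_params()],
#'   [load_config()]).
#' @param n cohort size (number of simulated individuals).
#' @param seed master seed; the run is fully reproducible given
#'   `(params, n, seed)`.
#' @param sex `"all"`, `"female"` or `"male"` — subgroup restriction.
#' @param min_age minimum entry age (e.g. 70 for the elderly subgroup).
#' @param prevalence_mode optionally override the prevalence scenario
#'   (`"fixed"` or `"age_specific"`).
#' @return object of class `osteo_cea` with components `arms` (both
#'   `arm_outcome`s), `incremental`, `per_10k`, and run metadata.
#' @examples
#' res <- run_model(n = 2000, seed = 42)
#' res
#' @export
run_model <- function(params = default_params(), n = 10000, seed = 1,
                      sex = c("all", "female", "male"), min_age = 50,
                      prevalence_mode = NULL) {
  sex <- match.arg(sex)
  if (!is.null(prevalence_mode)) {
    stopifnot(prevalence_mode %in% c("fixed", "age_specific"))
    params$prevalence$mode <- prevalence_mode
  }
  viol <- validate_params(params)
  if (length(viol) > 0)
    stop("invalid parameters:\n", paste(" -", viol, collapse = "\n"))
  if (sex != "all") {
    params$population$sex_shares <-
      stats::setNames(as.numeric(SEXES == sex), SEXES)
  }
  roster <- make_population(n, params$population, seed, min_age = min_age)
  osteo <- assign_osteoporosis(roster, params$prevalence, seed)
  arms <- run_cohort(roster, osteo, params, seed)
  inc <- incremental(arms$screening, arms$no_screening)
  out <- list(arms = arms, incremental = inc, per_10k = per_10k(inc),
              n = n, seed = seed, sex = sex, min_age = min_age,
              prevalence_mode = params$prevalence$mode,
              standins = standin_inputs(params),
              wtp = params$econ$wtp_thresholds)
  class(out) <- "osteo_cea"
  out
}

#' @export
print.osteo_cea <- function(x, ...) {
  cat("AI-based opportunistic osteoporosis screening vs no screening\n")
  cat(sprintf("  cohort: n = %s, sex = %s, min age = %d, prevalence = %s\n",
              format(x$n, big.mark = ","), x$sex, as.integer(x$min_age),
              x$prevalence_mode))
  print(x$incremental)
  wtp <- x$wtp[1]
  b <- nmb(x$incremental, wtp)
  cat(sprintf("  NMB at KRW %s/QALY: KRW %s (%s)\n",
              format(wtp, big.mark = ",", scientific = FALSE),
              format(round(b), big.mark = ","),
              if (b >= 0) "cost-effective" else "not cost-effective"))
  invisible(x)
}

#' @export
summary.osteo_cea <- function(object, ...) {
  s <- object$arms$screening; c0 <- object$arms$no_screening
  tab <- rbind(screening = c(s$mean, treated = s$treated_fraction),
               no_screening = c(c0$mean, treated = c0$treated_fraction))
  out <- list(arms = tab, incremental = object$incremental,
              per_10k = object$per_10k,
              fractures_by_site = rbind(screening = s$fractures_by_site,
                                        no_screening = c0$fractures_by_site),
              standins = object$standins)
  class(out) <- "summary.osteo_cea"
  out
}

#' @export
print.summary.osteo_cea <- function(x, ...) {
  cat("Per-arm mean outcomes (per person):\n")
  print(round(x$arms, 4))
  cat("\nMean lifetime fractures by site:\n")
  print(round(x$fractures_by_site, 5))
  cat("\n")
  print(x$per_10k)
  cat("\nSynthetic stand-in inputs used:",
      paste(x$standins, collapse = ", "), "\n")
  invisible(x)
}
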