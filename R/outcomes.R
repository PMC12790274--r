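# Incremental cost-effectiveness results: paired differences, ICER with
# dominance classification, per-10,000 scaling, net monetary benefit.

#' Incremental result of screening vs no screening
#'
#' Componentwise paired differences (screening minus comparator) with Monte
#' Carlo standard errors, and the ICER with dominance classification.
#' `delta_fractures` is reported as fractures averted (comparator minus
#' screening), so a positive value favours screening.
#'
#' @param screening,comparator `arm_outcome` objects from [run_cohort()],
#'   from the same roster and seed (checked).
#' @return object of class `osteo_incremental`: `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `delta_fractures` (averted), their paired SEs, `icer`, and
#'   `label` in `{"icer", "dominant", "dominated", "equivalent"}`.
#' @export
incremental <- function(screening, comparator) {
  stopifnot(inherits(screening, "arm_outcome"), inherits(comparator, "arm_outcome"))
  if (!identical(screening$cohort_id, comparator$cohort_id))
    stop("arm outcomes come from different cohorts; increments must be paired")
  d_cost <- screening$ind$cost - comparator$ind$cost
  d_qaly <- screening$ind$qaly - comparator$ind$qaly
  d_ly <- screening$ind$ly - comparator$ind$ly
  d_fr <- comparator$ind$fractures - screening$ind$fractures # averted
  n <- screening$n
  res <- list(
    n = n,
    delta_cost = mean(d_cost), delta_qaly = mean(d_qaly),
    delta_ly = mean(d_ly), delta_fractures = mean(d_fr),
    se = c(cost = stats::sd(d_cost), qaly = stats::sd(d_qaly),
           ly = stats::sd(d_ly), fractures = stats::sd(d_fr)) / sqrt(n))
  cls <- classify_icer(res$delta_cost, res$delta_qaly)
  res$label <- cls$label
  res$icer <- cls$icer
  class(res) <- "osteo_incremental"
  res
}

classify_icer <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0)
    return(list(label = "equivalent", icer = NA_real_))
  if (delta_qaly > 0 && delta_cost <= 0)
    return(list(label = "dominant", icer = NA_real_))
  if (delta_qaly <= 0 && delta_cost > 0)
    return(list(label = "dominated", icer = NA_real_))
  if (delta_qaly == 0) # delta_cost < 0
    return(list(label = "dominant", icer = NA_real_))
  list(label = "icer", icer = delta_cost / delta_qaly)
}

#' Scale an incremental result to a 10,000-person cohort
#'
#' Multiplies the per-person differences by 10,000; the ICER is
#' scale-invariant and unchanged.
#'
#' @param result an `osteo_incremental` object (per-person units).
#' @return the result with differences scaled, `per` attribute set to 10000.
#' @export
per_10k <- function(result) {
  stopifnot(inherits(result, "osteo_incremental"))
  out <- result
  for (f in c("delta_cost", "delta_qaly", "delta_ly", "delta_fractures"))
    out[[f]] <- result[[f]] * 1e4
  out$se <- result$se * 1e4
  out$per <- 1e4
  out
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`; non-negative NMB at a threshold is
#' equivalent to the ICER lying at or below it (when `delta_qaly > 0`).
#'
#' @param result an `osteo_incremental` object, or a list with `delta_cost`
#'   and `delta_qaly`.
#' @param wtp willingness-to-pay threshold(s), KRW per QALY; vectorised.
#' @return NMB in KRW.
#' @export
nmb <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$delta_qaly - result$delta_cost
}

#' @export
print.osteo_incremental <- function(x, ...) {
  per <- if (is.null(x$per)) 1 else x$per
  unit <- if (per == 1) "per person" else sprintf("per %s persons",
                                                 format(per, big.mark = ","))
  cat(sprintf("incremental result, screening vs no screening (%s)\n", unit))
  cat(sprintf("  delta cost      : KRW %s (SE %s)\n",
              format(round(x$delta_cost), big.mark = ","),
              format(round(x$se["cost"]), big.mark = ",")))
  cat(sprintf("  delta QALYs     : %.6g (SE %.3g)\n", x$delta_qaly, x$se["qaly"]))
  cat(sprintf("  delta life-years: %.6g\n", x$delta_ly))
  cat(sprintf("  fractures averted: %.6g\n", x$delta_fractures))
  if (x$label == "icer") {
    cat(sprintf("  ICER            : KRW %s per QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else cat(sprintf("  dominance       : %s\n", x$label))
  invisible(x)
}
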