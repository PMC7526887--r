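#' Quadrant of the cost-effectiveness plane
#'
#' Classifies an incremental pair on the plane with effect gain (AE-yield
#' percentage points, 2wT minus SoC) on the x-axis and cost change (USD per
#' client) on the y-axis: NE = more effective & more costly, SE = more
#' effective & less costly, SW = less effective & less costly, NW = less
#' effective & more costly. Exact zeros (measure-zero under continuous
#' sampling) are tie-broken deterministically: zero effect gain counts as the
#' "more effective" side and zero cost change as the "less costly" side, so
#' `(0, 0)` maps to SE.
#'
#' @param delta_cost Incremental cost (USD/client), 2wT minus SoC.
#' @param delta_yield Incremental AE yield (percentage points).
#' @return `"NE"`, `"SE"`, `"SW"` or `"NW"` (vectorized).
#' @export
#' @examples
#' classify_quadrant(-2.10, 50)  # "SE"
classify_quadrant <- function(delta_cost, delta_yield) {
  stopifnot(length(delta_cost) == length(delta_yield))
  east <- delta_yield >= 0
  south <- delta_cost <= 0
  ifelse(east, ifelse(south, "SE", "NE"), ifelse(south, "SW", "NW"))
}

#' Incremental cost-effectiveness analysis of 2wT vs SoC
#'
#' Differences are 2wT minus SoC throughout. When one strategy dominates
#' (less costly and more effective — SE means 2wT dominates, NW means SoC
#' does) no ICER is reported; in the trade-off quadrants (NE, SW) the ICERs
#' are the cost per percentage-point of AE yield and the cost per additional
#' AE ascertained per client. A zero effect gain with a nonzero cost change
#' sits on the axis and reports an infinite ICER rather than dividing by
#' zero.
#'
#' @param result A `twt_model_result` from [evaluate_model()], or the SoC
#'   cost breakdown (then `twt`, `ae_yield_soc`, `ae_yield_twt`, `ae_rates`
#'   must be supplied).
#' @param ... Unused.
#' @return A `twt_incremental`: `delta_cost`, `delta_yield` (points),
#'   `delta_aes` (AEs/client), `icer_per_point`, `icer_per_ae`, `verdict`,
#'   `quadrant`.
#' @export
incremental_analysis <- function(result, ...) {
  stopifnot(inherits(result, "twt_model_result"))
  delta_cost <- result$twt$total - result$soc$total
  delta_yield <- result$ae_yield[["twt"]] - result$ae_yield[["soc"]]
  delta_aes <- result$ae_rate[["twt"]] - result$ae_rate[["soc"]]
  quadrant <- classify_quadrant(delta_cost, delta_yield)
  verdict <- switch(quadrant,
                    SE = "twt_dominant", NW = "soc_dominant",
                    NE = "tradeoff_ne", SW = "tradeoff_sw")
  tradeoff <- quadrant %in% c("NE", "SW")
  icer_per_point <- if (!tradeoff) NA_real_
                    else if (delta_yield == 0) Inf
                    else delta_cost / delta_yield
  icer_per_ae <- if (!tradeoff) NA_real_
                 else if (delta_aes == 0) Inf
                 else delta_cost / delta_aes
  structure(
    list(delta_cost = delta_cost, delta_yield = delta_yield,
         delta_aes = delta_aes, icer_per_point = icer_per_point,
         icer_per_ae = icer_per_ae, verdict = verdict, quadrant = quadrant),
    class = "twt_incremental")
}

#' @export
print.twt_incremental <- function(x, ...) {
  cat("<incremental analysis, 2wT vs SoC>\n")
  cat(sprintf("  delta cost:  $%.2f/client\n", x$delta_cost))
  cat(sprintf("  delta yield: %+.0f points (%+.4f AEs/client)\n",
              x$delta_yield, x$delta_aes))
  if (x$verdict == "twt_dominant")
    cat("  verdict: 2wT dominant (less costly and more effective)\n")
  else if (x$verdict == "soc_dominant")
    cat("  verdict: SoC dominant (2wT more costly and less effective)\n")
  else
    cat(sprintf("  verdict: trade-off (%s); ICER $%.2f per yield point, $%.0f per AE\n",
                x$quadrant, x$icer_per_point, x$icer_per_ae))
  invisible(x)
}
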