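#' Moment-matched sampling distribution for a parameter
#'
#' Builds the probabilistic-sensitivity-analysis distribution of one
#' parameter from its baseline (taken as the mean) and range (taken as a 95%
#' interval, so the standard error is a quarter of its width): a beta
#' distribution for probabilities, gamma for costs and normal for everything
#' else, each matched to `(mean, se)` in closed form. Fixed parameters and
#' zero-width ranges yield a point mass. Asymmetric empirical ranges still
#' anchor the mean at the baseline.
#'
#' @param p A `twt_parameter`.
#' @return A `twt_distribution`: `name`, `family` (`"beta"`, `"gamma"`,
#'   `"normal"` or `"point"`), `mean`, `se`, and the derived shape
#'   parameters.
#' @export
#' @examples
#' fit_distribution(parameter("p", 0.5, 0.3, 0.7, "probability"))  # beta(12, 12)
#' fit_distribution(parameter("c", 10, 5, 15, "cost"))  # gamma(16, scale 0.625)
fit_distribution <- function(p) {
  stopifnot(inherits(p, "twt_parameter"))
  m <- p$baseline
  se <- if (p$fixed || !is.finite(p$low)) 0 else (p$high - p$low) / 4
  d <- list(name = p$name, mean = m, se = se)
  if (se == 0) {
    d$family <- "point"
  } else if (p$category == "probability") {
    v <- se^2
    if (v >= m * (1 - m))
      stop(sprintf(
        "parameter '%s': beta moment matching infeasible (se^2 = %g >= m(1-m) = %g)",
        p$name, v, m * (1 - m)), call. = FALSE)
    k <- m * (1 - m) / v - 1
    d$family <- "beta"; d$shape1 <- m * k; d$shape2 <- (1 - m) * k
  } else if (p$category == "cost") {
    if (m <= 0)
      stop(sprintf("parameter '%s': gamma moment matching needs mean > 0", p$name),
           call. = FALSE)
    d$family <- "gamma"; d$shape <- m^2 / se^2; d$scale <- se^2 / m
  } else {
    d$family <- "normal"
  }
  structure(d, class = "twt_distribution")
}

#' Draw from a fitted distribution
#'
#' Samples the distribution exactly as fitted (so sample moments converge to
#' `(mean, se)`). Truncation of normal draws at zero — needed because times,
#' FTEs and counts are strictly positive quantities — is applied by
#' resampling when `truncate_at_zero = TRUE`, which [run_psa()] sets.
#'
#' @param d A `twt_distribution`.
#' @param n Number of draws.
#' @param truncate_at_zero Resample non-positive normal draws (default
#'   `FALSE`).
#' @return Numeric vector of length `n`.
#' @export
draw_distribution <- function(d, n, truncate_at_zero = FALSE) {
  stopifnot(inherits(d, "twt_distribution"))
  switch(d$family,
    point = rep(d$mean, n),
    beta = stats::rbeta(n, d$shape1, d$shape2),
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
    normal = {
      x <- stats::rnorm(n, d$mean, d$se)
      if (truncate_at_zero) {
        while (any(bad <- x <= 0))
          x[bad] <- stats::rnorm(sum(bad), d$mean, d$se)
      }
      x
    })
}

#' One-way (tornado) sensitivity analysis
#'
#' Moves each non-fixed parameter to its low and high bound in turn, all
#' others held at baseline, and records the model output at both ends. The
#' swing — the absolute width of the output interval — ranks parameters by
#' influence; entries come back sorted by descending swing. The default
#' output is the incremental cost of 2wT versus SoC (USD/client).
#'
#' @param pt A complete `twt_parameter_table`.
#' @param output Function of a parameter table returning one number. The
#'   default is incremental cost; pass e.g. the incremental AE yield for an
#'   effect-side tornado.
#' @param top Keep only the `top` largest swings (default all).
#' @param include_ae_management Passed to the default output's
#'   [evaluate_model()] call.
#' @return A `data.frame` (`parameter`, `low_input`, `high_input`,
#'   `output_at_low`, `output_at_high`, `swing`) sorted by descending swing.
#' @export
one_way <- function(pt, output = NULL, top = NULL,
                    include_ae_management = TRUE) {
  stopifnot(inherits(pt, "twt_parameter_table"))
  if (is.null(output))
    output <- function(p)
      incremental_analysis(evaluate_model(p, include_ae_management))$delta_cost
  varied <- Filter(function(p) !p$fixed, pt)
  rows <- lapply(varied, function(p) {
    at <- function(v) output(set_values(pt, stats::setNames(v, p$name)))
    lo <- at(p$low); hi <- at(p$high)
    data.frame(parameter = p$name, low_input = p$low, high_input = p$high,
               output_at_low = lo, output_at_high = hi,
               swing = abs(hi - lo), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res <- res[order(-res$swing, res$parameter), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(top)) res <- utils::head(res, top)
  res
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Propagates joint parameter uncertainty: each simulation draws every
#' non-fixed parameter once from its fitted distribution ([fit_distribution()];
#' a parameter shared between arms, e.g. the nurse wage, uses the same draw
#' in both), evaluates both arms, and records the incremental pair
#' (AE-yield points gained, cost change in USD/client) and its quadrant.
#' Normal draws are truncated at zero by resampling. Reproducible given
#' `(seed, n_sims)`.
#'
#' @param pt A complete `twt_parameter_table`.
#' @param n_sims Number of simulations (default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @param include_ae_management Passed to [evaluate_model()].
#' @return A `twt_psa`: `pairs` data.frame (`sim`, `delta_yield_points`,
#'   `delta_cost_usd`, `quadrant`), `quadrant_proportions` (named fractions
#'   summing to 1), `n_sims`, `seed`, and the base-case incremental result.
#' @export
run_psa <- function(pt, n_sims = 1000, seed, include_ae_management = TRUE) {
  stopifnot(inherits(pt, "twt_parameter_table"), n_sims >= 1)
  if (missing(seed)) stop("run_psa() requires an explicit seed", call. = FALSE)
  set.seed(as.integer(seed))
  varied <- Filter(function(p) !p$fixed, pt)
  draws <- matrix(numeric(0), nrow = n_sims, ncol = 0)
  if (length(varied)) {
    draws <- vapply(varied, function(p)
      draw_distribution(fit_distribution(p), n_sims, truncate_at_zero = TRUE),
      numeric(n_sims))
    if (n_sims == 1) draws <- matrix(draws, nrow = 1,
                                     dimnames = list(NULL, names(varied)))
  }
  sims <- lapply(seq_len(n_sims), function(i) {
    inc <- incremental_analysis(
      evaluate_model(set_values(pt, draws[i, ]), include_ae_management))
    c(delta_yield_points = inc$delta_yield, delta_cost_usd = inc$delta_cost)
  })
  pairs <- as.data.frame(do.call(rbind, sims))
  pairs <- cbind(sim = seq_len(n_sims), pairs)
  pairs$quadrant <- classify_quadrant(pairs$delta_cost_usd,
                                      pairs$delta_yield_points)
  props <- vapply(c("NE", "SE", "SW", "NW"),
                  function(q) mean(pairs$quadrant == q), 0)
  structure(
    list(pairs = pairs, quadrant_proportions = props,
         n_sims = n_sims, seed = as.integer(seed),
         base = incremental_analysis(
           evaluate_model(pt, include_ae_management))),
    class = "twt_psa")
}

#' @export
print.twt_psa <- function(x, ...) {
  cat(sprintf("<PSA> %d simulations (seed %d)\n", x$n_sims, x$seed))
  p <- 100 * x$quadrant_proportions
  cat(sprintf("  quadrants: SE %.1f%%, NE %.1f%%, SW %.1f%%, NW %.1f%%\n",
              p[["SE"]], p[["NE"]], p[["SW"]], p[["NW"]]))
  cat(sprintf("  base case: delta cost $%.2f, delta yield %+.0f points (%s)\n",
              x$base$delta_cost, x$base$delta_yield, x$base$verdict))
  invisible(x)
}
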