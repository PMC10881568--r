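#' Population allele-size model for the HTT CAG repeat
#'
#' A discrete distribution of CAG repeat counts on an inclusive integer
#' support. The default is a discretized, truncated log-normal centred at
#' 17 repeats with a long right tail, placing about 6% of alleles in the
#' intermediate band (27-35 repeats) in line with reported population
#' frequencies of intermediate alleles. No openly available allele
#' frequency table exists for the study populations this emulates, so the
#' default is an explicit stand-in: both the support and the weights are
#' fully configurable.
#'
#' @param support Inclusive integer range of CAG counts (default `9:55`).
#'   Lower bound must be at least 1.
#' @param weights Optional non-negative relative frequency per count
#'   (same length as `support`); normalized to sum to 1. When `NULL`,
#'   weights are log-normal bin masses
#'   `plnorm(c + 0.5, meanlog, sdlog) - plnorm(c - 0.5, meanlog, sdlog)`.
#' @param meanlog,sdlog Log-normal parameters used when `weights` is
#'   `NULL`. Defaults `log(17)` and `0.30`.
#' @return An object of class `"allele_model"`: list with `support`,
#'   `weights` (normalized) and `intermediate_prob`, the total mass on
#'   27-35 repeats.
#' @examples
#' m <- allele_model()
#' m$intermediate_prob      # ~0.06
#' allele_model_mean(m)
#' @seealso [sample_allele()], [shift_allele_model()], [generate_cohort()]
#' @export
allele_model <- function(support = 9:55, weights = NULL,
                         meanlog = log(17), sdlog = 0.30) {
  if (length(support) == 0L) {
    stop_httcag("allele model support is empty")
  }
  if (any(support != round(support))) {
    stop_httcag("allele model support must be integer CAG counts")
  }
  support <- as.integer(sort(unique(support)))
  if (support[1L] < 1L) {
    stop_httcag("allele model support lower bound must be >= 1 (got %d)",
                support[1L])
  }
  if (is.null(weights)) {
    weights <- stats::plnorm(support + 0.5, meanlog, sdlog) -
      stats::plnorm(support - 0.5, meanlog, sdlog)
  }
  if (length(weights) != length(support)) {
    stop_httcag("weights length (%d) must match support length (%d)",
                length(weights), length(support))
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_httcag("allele weights must be finite and non-negative")
  }
  total <- sum(weights)
  if (total <= 0) {
    stop_httcag("allele weights sum to zero; empty distribution")
  }
  weights <- weights / total
  structure(
    list(
      support = support,
      weights = weights,
      intermediate_prob = sum(weights[support >= 27L & support <= 35L])
    ),
    class = "allele_model"
  )
}

#' @export
print.allele_model <- function(x, ...) {
  cat(sprintf(
    "<allele_model> support %d..%d, mean %.2f, P(27-35) = %.4f\n",
    min(x$support), max(x$support), allele_model_mean(x),
    x$intermediate_prob
  ))
  invisible(x)
}

#' Analytic mean CAG count of an allele model
#'
#' @param model An [allele_model()].
#' @return `sum(support * weights)`.
#' @export
allele_model_mean <- function(model) {
  stopifnot(inherits(model, "allele_model"))
  sum(model$support * model$weights)
}

#' Draw CAG allele sizes from an allele model
#'
#' Uses R's global random number stream; seed with `set.seed()` (or let
#' [generate_cohort()] manage per-group streams).
#'
#' @param model An [allele_model()].
#' @param n Number of draws.
#' @return Integer vector of CAG counts within the model support.
#' @export
sample_allele <- function(model, n = 1L) {
  stopifnot(inherits(model, "allele_model"), is_count(n))
  if (n == 0L) return(integer(0))
  if (length(model$support) == 1L) {
    return(rep(model$support, n))
  }
  sample(model$support, size = n, replace = TRUE, prob = model$weights)
}

#' Shift the mean of an allele model by a (possibly fractional) amount
#'
#' A shift of `delta` repeats is realized exactly on the discrete weight
#' table: mass at count `c` moves to `c + floor(delta)` with probability
#' `1 - frac` and to `c + floor(delta) + 1` with probability
#' `frac = delta - floor(delta)`. The analytic mean of the shifted model
#' is therefore exactly `allele_model_mean(model) + delta`, so an
#' injected per-allele shift of delta moves the expected per-individual
#' sum of repeats by exactly `2 * delta`.
#'
#' @param model An [allele_model()].
#' @param delta Shift in repeat units; may be fractional or negative. The
#'   shifted support must stay at or above 1 repeat.
#' @return A new [allele_model()] on the shifted support.
#' @export
shift_allele_model <- function(model, delta) {
  stopifnot(inherits(model, "allele_model"),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (delta == 0) return(model)
  lo <- floor(delta)
  frac <- delta - lo
  new_min <- min(model$support) + lo
  if (new_min < 1L) {
    stop_httcag("mean shift %.3f pushes support below 1 repeat", delta)
  }
  counts <- (min(model$support) + lo):(max(model$support) + lo + (frac > 0))
  w <- numeric(length(counts))
  idx <- match(model$support + lo, counts)
  w[idx] <- w[idx] + model$weights * (1 - frac)
  if (frac > 0) {
    idx2 <- match(model$support + lo + 1L, counts)
    w[idx2] <- w[idx2] + model$weights * frac
  }
  keep <- w > 0
  allele_model(support = counts[keep], weights = w[keep])
}

# Restrict a model to a subset of its support (logical mask over support).
# Errors when the retained mass is zero, naming `what` for context.
restrict_allele_model <- function(model, keep, what) {
  if (!any(keep) || sum(model$weights[keep]) <= 0) {
    stop_httcag("allele model has no probability mass on %s", what)
  }
  allele_model(support = model$support[keep],
               weights = model$weights[keep])
}
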