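#' Four-parameter sigmoidal Emax curve parameters
#'
#' Bundles the four parameters of the sigmoid-Emax event-probability curve
#' \deqn{p(x) = p_{lo} + (p_{hi} - p_{lo}) \frac{x^{h}}{ED_{50}^{h} + x^{h}},}
#' where `p_lo` is the floor probability approached at vanishing dose,
#' `p_hi` the ceiling probability approached at very large dose, `ed50`
#' the dose at which the curve sits halfway between floor and ceiling, and
#' `hill` the steepness of the S-curve. `p_hi < p_lo` is permitted and
#' encodes a curve that *decreases* with dose; `p_hi = p_lo` is a flat
#' curve. Dose `x` is expected on the ordinal dose-level scale (1..K) used
#' throughout the package, so `ed50` and `hill` live on that scale too.
#'
#' @param p_lo Floor probability in \[0, 1\].
#' @param p_hi Ceiling probability in \[0, 1\].
#' @param ed50 Positive location of the S-curve on the dose-level scale.
#' @param hill Positive steepness (Hill coefficient).
#' @return An object of class `emax_params`.
#' @examples
#' th <- emax_params(p_lo = 0.1, p_hi = 0.5, ed50 = 2, hill = 1.5)
#' emax_prob(th, 1:4)
#' @export
emax_params <- function(p_lo, p_hi, ed50, hill) {
  for (nm in c("p_lo", "p_hi", "ed50", "hill")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (p_lo < 0 || p_lo > 1) stop("`p_lo` must lie in [0, 1]", call. = FALSE)
  if (p_hi < 0 || p_hi > 1) stop("`p_hi` must lie in [0, 1]", call. = FALSE)
  if (ed50 <= 0) stop("`ed50` must be positive", call. = FALSE)
  if (hill <= 0) stop("`hill` must be positive", call. = FALSE)
  structure(
    list(p_lo = p_lo, p_hi = p_hi, ed50 = ed50, hill = hill),
    class = "emax_params"
  )
}

#' @export
print.emax_params <- function(x, ...) {
  cat(sprintf(
    "<emax_params> p_lo = %.4g, p_hi = %.4g, ed50 = %.4g, hill = %.4g\n",
    x$p_lo, x$p_hi, x$ed50, x$hill
  ))
  invisible(x)
}

#' Evaluate the Emax event-probability curve
#'
#' Computed as `p_lo + (p_hi - p_lo) * plogis(hill * (log(x) - log(ed50)))`,
#' which is algebraically identical to the ratio form
#' `x^hill / (ed50^hill + x^hill)` but stable for large Hill coefficients.
#' The value always lies between the two asymptotes, equals their midpoint
#' at `x = ed50`, and is monotone in `x` with direction `sign(p_hi - p_lo)`.
#' With `p_lo = 0, p_hi = 1` the curve is exactly the logistic function of
#' `hill * (log x - log ed50)` — the logit-model special case in which the
#' event probability is driven to 1 at large dose.
#'
#' @param params An [emax_params] object.
#' @param x Vector of positive dose levels.
#' @return Vector of event probabilities, same length as `x`.
#' @export
emax_prob <- function(params, x) {
  stopifnot(inherits(params, "emax_params"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("dose level `x` must be positive and finite", call. = FALSE)
  }
  params$p_lo + (params$p_hi - params$p_lo) *
    stats::plogis(params$hill * (log(x) - log(params$ed50)))
}

#' Binomial log-likelihood of an Emax curve for an analysis series
#'
#' Sums `events * log p + (n - events) * log(1 - p)` over the dose levels of
#' the series, with the convention `0 * log(0) = 0`, so the result is `-Inf`
#' exactly when the curve asserts an impossible cell (probability 0 with
#' events observed, or probability 1 with non-events observed). The binomial
#' combinatorial constant is omitted: it does not depend on the parameters,
#' and dropping it keeps the ML objective and the Bayesian log-posterior on
#' the same scale.
#'
#' @param params An [emax_params] object.
#' @param series An [analysis_series] with at least two dose levels.
#' @return A single log-likelihood value (possibly `-Inf`).
#' @export
emax_loglik <- function(params, series) {
  stopifnot(inherits(params, "emax_params"))
  series <- as_analysis_series(series)
  if (!is_fittable(series)) {
    stop("series is not fittable: fewer than two dose levels", call. = FALSE)
  }
  p <- emax_prob(params, series$points$level)
  binom_loglik(p, series$points$n, series$points$events)
}

# shared kernel: sum of binomial log-terms with 0*log(0) = 0
binom_loglik <- function(p, n, events) {
  ll <- 0
  ev <- events > 0
  nv <- events < n
  if (any(ev)) ll <- ll + sum(events[ev] * log(p[ev]))
  if (any(nv)) ll <- ll + sum((n - events)[nv] * log1p(-p[nv]))
  ll
}

#' Curve height: fitted probability at the top dose minus the bottom dose
#'
#' The monotonicity statistic: `emax_prob` at the highest investigated level
#' minus `emax_prob` at the lowest. Positive heights mean the event becomes
#' more probable as dose increases; the height is 0 exactly when the curve
#' is flat, and always lies in \[-1, 1\].
#'
#' @param params An [emax_params] object.
#' @param levels Numeric vector of at least two positive dose levels.
#' @return A single number in \[-1, 1\].
#' @examples
#' curve_height(emax_params(0, 1, 2, 2), levels = 1:4)  # 0.8 - 0.2
#' @export
curve_height <- function(params, levels) {
  if (length(levels) < 2L) {
    stop("curve height needs at least two dose levels", call. = FALSE)
  }
  emax_prob(params, max(levels)) - emax_prob(params, min(levels))
}
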