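#' Fit every fittable series in a list
#'
#' Convenience wrapper for the corpus-level workflow: filters to fittable
#' series (>= 2 dose levels) and fits each with [fit_bayes] or [fit_mle].
#' Per-series seeds are derived deterministically from `seed`, so the whole
#' batch is reproducible.
#'
#' @param series List of [analysis_series], e.g. from [build_all_series].
#' @param method `"bayes"` or `"mle"`.
#' @param seed Integer master seed (Bayesian fits).
#' @param ... Passed on to the fitting function.
#' @return List of fit objects, one per fittable series.
#' @export
fit_all_series <- function(series, method = c("bayes", "mle"), seed = 1, ...) {
  method <- match.arg(method)
  series <- Filter(is_fittable, series)
  if (length(series) == 0L) return(list())
  set.seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- sample.int(2^31 - 2, length(series))
  lapply(seq_along(series), function(i) {
    if (method == "bayes") {
      fit_bayes(series[[i]], seed = seeds[i], ...)
    } else {
      fit_mle(series[[i]], ...)
    }
  })
}
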