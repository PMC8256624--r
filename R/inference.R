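#' Prior specification for Bayesian Emax fitting
#'
#' The floor and ceiling probabilities always get independent Uniform(0, 1)
#' priors, so every event probability at the lowest and highest doses is a
#' priori equally likely. The location and steepness parameters get weakly
#' informative positive-support priors whose only job is to keep estimation
#' in the feasible region:
#'
#' * `ed50 ~ LogNormal(ed50_meanlog, ed50_sdlog)`, by default centred at the
#'   middle dose level `(k_levels + 1) / 2` with log-scale spread 1, so the
#'   one-sd range covers the investigated levels;
#' * `hill ~ HalfNormal(hill_scale)`, by default scale 5, which keeps most
#'   mass on gentle slopes while still permitting near-step transitions over
#'   a single level span.
#'
#' All hyperparameters are configurable; draws from the prior always satisfy
#' the parameter-space constraints.
#'
#' @param k_levels Number of dose levels the series spans (sets the default
#'   `ed50` centre).
#' @param ed50_meanlog,ed50_sdlog Log-normal hyperparameters for `ed50`.
#' @param hill_scale Half-normal scale for `hill`.
#' @return An object of class `emax_priors`.
#' @export
emax_priors <- function(k_levels = 4,
                        ed50_meanlog = log((k_levels + 1) / 2),
                        ed50_sdlog = 1,
                        hill_scale = 5) {
  stopifnot(k_levels >= 2, ed50_sdlog > 0, hill_scale > 0)
  structure(
    list(ed50_meanlog = ed50_meanlog, ed50_sdlog = ed50_sdlog,
         hill_scale = hill_scale),
    class = "emax_priors"
  )
}

# ---- internal parameterisation -------------------------------------------
# Unconstrained working scale theta = (logit p_lo, logit p_hi, log ed50,
# log hill); priors are expressed as densities of theta (Jacobian included).

theta_to_params <- function(theta) {
  emax_params(
    p_lo = stats::plogis(theta[1]), p_hi = stats::plogis(theta[2]),
    ed50 = exp(theta[3]), hill = exp(theta[4])
  )
}

params_to_theta <- function(params) {
  c(stats::qlogis(params$p_lo), stats::qlogis(params$p_hi),
    log(params$ed50), log(params$hill))
}

theta_loglik <- function(theta, levels, n, events) {
  p_lo <- stats::plogis(theta[1])
  p_hi <- stats::plogis(theta[2])
  p <- p_lo + (p_hi - p_lo) * stats::plogis(exp(theta[4]) * (log(levels) - theta[3]))
  binom_loglik(p, n, events)
}

theta_logprior <- function(theta, priors) {
  hill <- exp(theta[4])
  stats::dlogis(theta[1], log = TRUE) +          # uniform p_lo pushed to logit
    stats::dlogis(theta[2], log = TRUE) +        # uniform p_hi pushed to logit
    stats::dnorm(theta[3], priors$ed50_meanlog, priors$ed50_sdlog, log = TRUE) +
    stats::dnorm(hill, 0, priors$hill_scale, log = TRUE) + log(2) + theta[4]
}

sample_prior <- function(priors, n) {
  cbind(
    p_lo = stats::runif(n),
    p_hi = stats::runif(n),
    ed50 = stats::rlnorm(n, priors$ed50_meanlog, priors$ed50_sdlog),
    hill = abs(stats::rnorm(n, 0, priors$hill_scale))
  )
}

# ---- maximum likelihood ---------------------------------------------------

#' Fit an Emax curve by maximum likelihood
#'
#' Maximises the binomial log-likelihood over the transformed parameter
#' space from a fixed deterministic lattice of starting points (all
#' combinations of low/mid/high floor and ceiling, two `ed50` and two
#' `hill` values), keeping the best finite optimum. Standard errors come
#' from the observed information (inverted Hessian at the optimum, mapped
#' to the natural scale by the delta method) when the Hessian is
#' invertible. Because the four-parameter model is frequently
#' over-parameterised for the very small series typical of dose-finding
#' trials, failure is an expected outcome and is *flagged*, never raised:
#' `no_convergence` when no start yields a finite converged optimum,
#' `se_explosion` when the information matrix is singular or any standard
#' error on the probability or dose-level scale (`p_lo`, `p_hi`, `ed50`)
#' exceeds `se_threshold`, and `boundary` when
#' the optimum sits at the edge of the feasible region (asymptotes pinned
#' to 0/1 or a degenerate slope).
#'
#' @param series A fittable [analysis_series].
#' @param se_threshold Standard-error magnitude (probability / level scale)
#'   beyond which the fit is declared exploded; default 10.
#' @param maxit Optimiser iteration cap per start.
#' @return An object of class `emax_mle_fit`: `params`, `std_errors`
#'   (named, `NA` when unavailable), `loglik`, `converged`,
#'   `failure_reason`, and the `levels` of the series.
#' @export
fit_mle <- function(series, se_threshold = 10, maxit = 500) {
  series <- as_analysis_series(series)
  if (!is_fittable(series)) {
    stop("series is not fittable: fewer than two dose levels", call. = FALSE)
  }
  pts <- series$points
  levels <- pts$level
  kmax <- max(levels)

  neg <- function(theta) {
    v <- theta_loglik(theta, levels, pts$n, pts$events)
    if (!is.finite(v)) 1e10 else -v
  }

  asym <- stats::qlogis(c(0.1, 0.5, 0.9))
  starts <- expand.grid(
    t1 = asym, t2 = asym,
    t3 = log(c(kmax / 3, 2 * kmax / 3)),
    t4 = log(c(0.5, 3))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), neg, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(o) || !is.finite(o$value) || o$value >= 1e9) next
    if (is.null(best) || o$value < best$value) best <- o
  }

  if (is.null(best)) {
    mid <- theta_to_params(c(0, 0, log((kmax + 1) / 2), 0))
    return(new_mle_fit(mid, rep(NA_real_, 4), -Inf, FALSE, "no_convergence",
                       levels, series))
  }

  theta <- best$par
  params <- theta_to_params(theta)
  loglik <- -best$value

  on_boundary <- abs(theta[1]) > 7 || abs(theta[2]) > 7 ||
    theta[4] > log(150) || abs(theta[3] - log((kmax + 1) / 2)) > log(1e3)

  se_nat <- rep(NA_real_, 4)
  reason <- "none"
  H <- tryCatch(stats::optimHess(theta, neg), error = function(e) NULL)
  cov_theta <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(cov_theta) || any(!is.finite(diag(cov_theta))) || any(diag(cov_theta) < 0)) {
    reason <- "se_explosion"
  } else {
    jac <- c(params$p_lo * (1 - params$p_lo),
             params$p_hi * (1 - params$p_hi),
             params$ed50, params$hill)
    se_nat <- sqrt(diag(cov_theta)) * jac
    # explosion is judged on the probability- and level-scale parameters;
    # the dimensionless hill SE is reported but not thresholded
    if (any(se_nat[1:3] > se_threshold)) reason <- "se_explosion"
  }
  if (on_boundary) reason <- "boundary"
  if (best$convergence != 0) reason <- "no_convergence"

  new_mle_fit(params, se_nat, loglik, reason == "none", reason, levels, series)
}

new_mle_fit <- function(params, se, loglik, converged, reason, levels, series) {
  names(se) <- c("p_lo", "p_hi", "ed50", "hill")
  structure(
    list(params = params, std_errors = se, loglik = loglik,
         converged = converged, failure_reason = reason, levels = levels,
         series_id = series$series_id, study_id = series$study_id,
         outcome = series$outcome),
    class = "emax_mle_fit"
  )
}

#' @export
print.emax_mle_fit <- function(x, ...) {
  cat(sprintf("<emax_mle_fit> loglik = %.4g, converged = %s (%s)\n",
              x$loglik, x$converged, x$failure_reason))
  print(x$params)
  invisible(x)
}

# ---- Bayesian fit ---------------------------------------------------------

#' Fit an Emax curve by Bayesian posterior sampling
#'
#' Samples the joint posterior of the four curve parameters under
#' [emax_priors] with an adaptive random-walk Metropolis algorithm on the
#' transformed (unconstrained) scale. During warmup the proposal is adapted
#' twice over: the global step size is tuned towards an acceptance rate of
#' about 30%, and the proposal covariance is refreshed from the accumulated
#' warmup history; adaptation is frozen before the retained draws, which
#' keeps the chain Markovian where it counts. Chains start from independent
#' prior draws. Because the prior is proper, the posterior is proper for
#' *any* series — including all-zero and all-event cells where maximum
#' likelihood degenerates — so this routine returns a usable fit whenever
#' the series is fittable. Output is bit-reproducible given `(seed,
#' settings)`.
#'
#' @param series A fittable [analysis_series].
#' @param priors An [emax_priors]; default is `emax_priors(k)` for the
#'   series' number of levels.
#' @param chains Number of chains (default 2).
#' @param warmup Adaptation iterations per chain, discarded (default 500).
#' @param draws Retained draws per chain (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class `emax_bayes_fit`: `draws` (matrix with
#'   columns `p_lo`, `p_hi`, `ed50`, `hill`, all chains stacked), `chain`
#'   index per draw, `levels`, `seed`, `priors`, and a `diagnostics` tibble
#'   with per-parameter split-R-hat and effective sample size plus the
#'   per-chain acceptance rates.
#' @export
fit_bayes <- function(series, priors = NULL, chains = 2, warmup = 500,
                      draws = 1000, seed = 1) {
  series <- as_analysis_series(series)
  if (!is_fittable(series)) {
    stop("series is not fittable: fewer than two dose levels", call. = FALSE)
  }
  pts <- series$points
  levels <- pts$level
  if (is.null(priors)) priors <- emax_priors(max(levels))
  stopifnot(inherits(priors, "emax_priors"), chains >= 1, draws >= 100)

  logpost <- function(theta) {
    theta_loglik(theta, levels, pts$n, pts$events) + theta_logprior(theta, priors)
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  total <- warmup + draws
  all_draws <- vector("list", chains)
  acc_rates <- numeric(chains)

  for (ch in seq_len(chains)) {
    init <- sample_prior(priors, 1)[1, ]
    theta <- c(stats::qlogis(pmin(pmax(init["p_lo"], 1e-4), 1 - 1e-4)),
               stats::qlogis(pmin(pmax(init["p_hi"], 1e-4), 1 - 1e-4)),
               log(init["ed50"]), log(max(init["hill"], 1e-4)))
    names(theta) <- NULL
    lp <- logpost(theta)
    log_step <- log(0.5)
    chol_prop <- diag(4)
    hist <- matrix(NA_real_, warmup, 4)
    kept <- matrix(NA_real_, draws, 4)
    n_acc <- 0L

    for (t in seq_len(total)) {
      prop <- theta + exp(log_step) * as.numeric(chol_prop %*% stats::rnorm(4))
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        acc <- 1
      } else {
        acc <- 0
      }
      if (t <= warmup) {
        hist[t, ] <- theta
        # Robbins-Monro step-size tuning towards ~30% acceptance
        log_step <- log_step + (acc - 0.3) / sqrt(t)
        if (t >= 100 && t %% 100 == 0) {
          cv <- stats::cov(hist[seq_len(t), , drop = FALSE])
          cv <- cv + diag(1e-6, 4)
          ch_try <- tryCatch(t(chol(cv)), error = function(e) NULL)
          if (!is.null(ch_try)) chol_prop <- ch_try
        }
      } else {
        kept[t - warmup, ] <- theta
        n_acc <- n_acc + acc
      }
    }
    nat <- cbind(
      p_lo = stats::plogis(kept[, 1]), p_hi = stats::plogis(kept[, 2]),
      ed50 = exp(kept[, 3]), hill = exp(kept[, 4])
    )
    all_draws[[ch]] <- nat
    acc_rates[ch] <- n_acc / draws
  }

  mat <- do.call(rbind, all_draws)
  chain_id <- rep(seq_len(chains), each = draws)
  diag_tbl <- mcmc_diagnostics(all_draws)

  structure(
    list(draws = mat, chain = chain_id, levels = levels, seed = seed,
         priors = priors, diagnostics = diag_tbl, acceptance = acc_rates,
         n_chains = chains, n_draws = draws,
         series_id = series$series_id, study_id = series$study_id,
         outcome = series$outcome),
    class = "emax_bayes_fit"
  )
}

#' @export
print.emax_bayes_fit <- function(x, ...) {
  cat(sprintf("<emax_bayes_fit> %d draws x %d chains (seed %s)\n",
              x$n_draws, x$n_chains, format(x$seed)))
  cat("posterior means:", paste(sprintf("%s = %.3f", colnames(x$draws),
                                        colMeans(x$draws)), collapse = ", "), "\n")
  print(x$diagnostics)
  invisible(x)
}

# Split-R-hat and effective sample size per parameter, from a list of
# per-chain draw matrices (natural scale).
mcmc_diagnostics <- function(chain_list) {
  params <- colnames(chain_list[[1]])
  n <- nrow(chain_list[[1]])
  half <- floor(n / 2)
  res <- lapply(params, function(pm) {
    seqs <- list()
    for (m in chain_list) {
      v <- m[, pm]
      seqs <- c(seqs, list(v[seq_len(half)], v[(n - half + 1):n]))
    }
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, stats::var, numeric(1))
    w <- mean(vars)
    b <- half * stats::var(means)
    rhat <- if (w > 0) sqrt(((half - 1) / half * w + b / half) / w) else 1
    ess <- sum(vapply(chain_list, function(m) ess_one(m[, pm]), numeric(1)))
    tibble::tibble(param = pm, rhat = rhat, ess = ess)
  })
  dplyr::bind_rows(res)
}

# initial-positive-sequence autocorrelation ESS for one chain
ess_one <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) return(n)
  lag_max <- min(200L, n - 2L)
  rho <- stats::acf(v, lag.max = lag_max, plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

# ---- grid-quadrature posterior (independent oracle) -----------------------

#' Deterministic grid-quadrature posterior for an Emax series
#'
#' An entirely sampler-free approximation of the same posterior that
#' [fit_bayes] targets: each parameter is discretised on an
#' equal-prior-probability grid (prior quantiles at cell midpoints), so the
#' quadrature weight of each 4-D grid node is proportional to its
#' likelihood alone. Summaries of the parameters and of the curve height
#' follow by weighted averaging. Used as the independent cross-check of the
#' MCMC sampler; also handy for very small series where a fully
#' deterministic answer is preferred.
#'
#' @param series A fittable [analysis_series].
#' @param priors An [emax_priors]; default as in [fit_bayes].
#' @param grid_points Grid resolution per dimension (minimum 5, default 17;
#'   the grid has `grid_points^4` nodes).
#' @return A list: `param_means`, `height_mean`, `height_quantiles`
#'   (5%, 50%, 95%), and `n_grid`.
#' @export
posterior_from_grid <- function(series, priors = NULL, grid_points = 17) {
  series <- as_analysis_series(series)
  if (!is_fittable(series)) {
    stop("series is not fittable: fewer than two dose levels", call. = FALSE)
  }
  if (grid_points < 5) stop("grid too coarse: need grid_points >= 5", call. = FALSE)
  pts <- series$points
  levels <- pts$level
  if (is.null(priors)) priors <- emax_priors(max(levels))

  u <- (seq_len(grid_points) - 0.5) / grid_points
  g_p <- u                                            # Uniform(0,1) quantiles
  g_ed <- stats::qlnorm(u, priors$ed50_meanlog, priors$ed50_sdlog)
  g_hill <- priors$hill_scale * stats::qnorm(0.5 + u / 2)  # half-normal quantiles

  grid <- expand.grid(p_lo = g_p, p_hi = g_p, ed50 = g_ed, hill = g_hill,
                      KEEP.OUT.ATTRS = FALSE)
  ll <- rep(0, nrow(grid))
  for (i in seq_along(levels)) {
    p <- grid$p_lo + (grid$p_hi - grid$p_lo) *
      stats::plogis(grid$hill * (log(levels[i]) - log(grid$ed50)))
    e <- pts$events[i]
    nn <- pts$n[i]
    term <- rep(0, nrow(grid))
    if (e > 0) term <- term + e * log(p)
    if (e < nn) term <- term + (nn - e) * log1p(-p)
    ll <- ll + term
  }
  w <- exp(ll - max(ll))
  w <- w / sum(w)

  h <- (grid$p_hi - grid$p_lo) *
    (stats::plogis(grid$hill * (log(max(levels)) - log(grid$ed50))) -
       stats::plogis(grid$hill * (log(min(levels)) - log(grid$ed50))))

  list(
    param_means = c(
      p_lo = sum(w * grid$p_lo), p_hi = sum(w * grid$p_hi),
      ed50 = sum(w * grid$ed50), hill = sum(w * grid$hill)
    ),
    height_mean = sum(w * h),
    height_quantiles = weighted_quantile(h, w, c(0.05, 0.5, 0.95)),
    n_grid = nrow(grid)
  )
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o])
  out <- vapply(probs, function(p) x[o][which.max(cw >= p)], numeric(1))
  names(out) <- paste0(100 * probs, "%")
  out
}

# ---- prior predictive -----------------------------------------------------

#' Sample event-probability curves from the prior alone
#'
#' Draws parameter sets from [emax_priors] and pushes each through the Emax
#' curve at the given dose levels. Inspecting these candidate curves is the
#' standard check that the priors encode only very modest information: the
#' spread should cover flat, rising, and falling curves across the whole
#' probability range, with mean close to 0.5 at every level.
#'
#' @param priors An [emax_priors].
#' @param levels Positive dose levels to evaluate at.
#' @param n_curves Number of prior curves (>= 1).
#' @param seed Integer seed.
#' @return A list with `curves` (`n_curves` x `length(levels)` matrix of
#'   probabilities) and `params` (matrix of the sampled parameters).
#' @export
prior_predictive <- function(priors, levels, n_curves = 100, seed = 1) {
  stopifnot(inherits(priors, "emax_priors"), n_curves >= 1, all(levels > 0))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pars <- sample_prior(priors, n_curves)
  curves <- matrix(NA_real_, n_curves, length(levels))
  for (j in seq_along(levels)) {
    curves[, j] <- pars[, "p_lo"] + (pars[, "p_hi"] - pars[, "p_lo"]) *
      stats::plogis(pars[, "hill"] * (log(levels[j]) - log(pars[, "ed50"])))
  }
  colnames(curves) <- as.character(levels)
  list(curves = curves, params = pars)
}

# ---- fitted curves and heights -------------------------------------------

#' Fitted event-probability curve of an Emax fit
#'
#' For a converged maximum-likelihood fit, the point-estimate curve (always
#' monotone, being a single Emax evaluation); for a Bayesian fit, the
#' draw-wise posterior mean curve with a central credible interval at each
#' level.
#'
#' @param fit An `emax_mle_fit` or `emax_bayes_fit`.
#' @param levels Dose levels; defaults to the fit's own.
#' @param interval Central interval mass for Bayesian fits (default 0.9).
#' @return A tibble with columns `level`, `prob`, and for Bayesian fits
#'   `lower`, `upper`.
#' @export
fitted_curve <- function(fit, levels = NULL, interval = 0.9) {
  UseMethod("fitted_curve")
}

#' @export
fitted_curve.emax_mle_fit <- function(fit, levels = NULL, interval = 0.9) {
  if (!fit$converged) {
    stop("maximum-likelihood fit failed (", fit$failure_reason,
         "); use the Bayesian fit for this series", call. = FALSE)
  }
  if (is.null(levels)) levels <- fit$levels
  tibble::tibble(level = levels, prob = emax_prob(fit$params, levels))
}

#' @export
fitted_curve.emax_bayes_fit <- function(fit, levels = NULL, interval = 0.9) {
  if (is.null(levels)) levels <- fit$levels
  alpha <- (1 - interval) / 2
  d <- fit$draws
  out <- lapply(levels, function(x) {
    p <- d[, "p_lo"] + (d[, "p_hi"] - d[, "p_lo"]) *
      stats::plogis(d[, "hill"] * (log(x) - log(d[, "ed50"])))
    tibble::tibble(level = x, prob = mean(p),
                   lower = unname(stats::quantile(p, alpha)),
                   upper = unname(stats::quantile(p, 1 - alpha)))
  })
  dplyr::bind_rows(out)
}

#' Curve height of a fitted Emax model
#'
#' The fitted event probability at the highest level minus that at the
#' lowest. For maximum likelihood this is a scalar evaluated at the point
#' estimate; for a Bayesian fit the height is computed draw by draw, giving
#' a posterior distribution summarised by its mean and a central 90%
#' (configurable) interval.
#'
#' @param fit An `emax_mle_fit` or `emax_bayes_fit`.
#' @param levels Dose levels; defaults to the fit's own. At least two.
#' @param interval Central interval mass for Bayesian fits (default 0.9).
#' @return For MLE fits, a list with `value`; for Bayesian fits, a list
#'   with `draws`, `mean`, `lower`, `upper`, `interval`. Both carry class
#'   `curve_height_summary`.
#' @export
height_of_fit <- function(fit, levels = NULL, interval = 0.9) {
  UseMethod("height_of_fit")
}

#' @export
height_of_fit.emax_mle_fit <- function(fit, levels = NULL, interval = 0.9) {
  if (!fit$converged) {
    stop("maximum-likelihood fit failed (", fit$failure_reason,
         "); use the Bayesian fit for this series", call. = FALSE)
  }
  if (is.null(levels)) levels <- fit$levels
  v <- curve_height(fit$params, levels)
  structure(list(value = v, mean = v, method = "mle"),
            class = "curve_height_summary")
}

#' @export
height_of_fit.emax_bayes_fit <- function(fit, levels = NULL, interval = 0.9) {
  if (is.null(levels)) levels <- fit$levels
  if (length(levels) < 2L) stop("need at least two levels", call. = FALSE)
  d <- fit$draws
  h <- (d[, "p_hi"] - d[, "p_lo"]) *
    (stats::plogis(d[, "hill"] * (log(max(levels)) - log(d[, "ed50"]))) -
       stats::plogis(d[, "hill"] * (log(min(levels)) - log(d[, "ed50"]))))
  alpha <- (1 - interval) / 2
  structure(
    list(draws = h, mean = mean(h),
         lower = unname(stats::quantile(h, alpha)),
         upper = unname(stats::quantile(h, 1 - alpha)),
         interval = interval, method = "bayes"),
    class = "curve_height_summary"
  )
}

#' @export
print.curve_height_summary <- function(x, ...) {
  if (x$method == "mle") {
    cat(sprintf("<curve height> %.4f (maximum likelihood)\n", x$value))
  } else {
    cat(sprintf("<curve height> mean %.4f, %d%% interval [%.4f, %.4f]\n",
                x$mean, round(100 * x$interval), x$lower, x$upper))
  }
  invisible(x)
}
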