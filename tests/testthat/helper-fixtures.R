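# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive brute-force computations, independent of the package's own code
# paths.

worked_example_doses <- function() {
  list(
    dose_combination(c(A = 10, B = 20), "d1"),
    dose_combination(c(A = 20, B = 10), "d2"),
    dose_combination(c(A = 20, B = 20), "d3")
  )
}

diamond_doses <- function() {
  list(
    dose_combination(c(A = 10, B = 10), "d1"),
    dose_combination(c(A = 20, B = 10), "d2"),
    dose_combination(c(A = 10, B = 20), "d3"),
    dose_combination(c(A = 20, B = 20), "d4")
  )
}

# quick series builder
make_series <- function(n, events, outcome = "DLT", study = "s1") {
  analysis_series(study, outcome, n = n, events = events)
}

# oracle: binomial log-likelihood as an explicit per-patient Bernoulli sum
oracle_loglik <- function(params, series) {
  total <- 0
  for (i in seq_len(nrow(series$points))) {
    p <- emax_prob(params, series$points$level[i])
    e <- series$points$events[i]
    n <- series$points$n[i]
    for (j in seq_len(n)) {
      total <- total + if (j <= e) log(p) else log(1 - p)
    }
  }
  total
}

# oracle: longest-chain length by exhaustive subset search
bf_longest_chain <- function(doses) {
  n <- length(doses)
  is_chain <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    for (a in idx) for (b in idx) {
      if (a < b && compare_doses(doses[[a]], doses[[b]]) == "incomparable") {
        return(FALSE)
      }
    }
    TRUE
  }
  best <- 1
  for (m in seq_len(n)) {
    for (idx in utils::combn(n, m, simplify = FALSE)) {
      if (is_chain(idx)) best <- max(best, m)
    }
  }
  best
}

# oracle: optimal cover of the dose set by inclusion-maximal chains,
# minimising total repetitions then breaking ties lexicographically on the
# sorted chain-label sequences. Exhaustive over all subsets of maximal
# chains; returns list of ascending index vectors, NULL if too large.
bf_chain_cover <- function(doses) {
  n <- length(doses)
  rel <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    rel[a, b] <- compare_doses(doses[[a]], doses[[b]]) == "less"
  }
  # all chains as sorted index sets, via subset enumeration
  chains <- list()
  for (m in seq_len(n)) {
    for (idx in utils::combn(n, m, simplify = FALSE)) {
      ok <- TRUE
      for (a in idx) for (b in idx) {
        if (a != b && !rel[a, b] && !rel[b, a]) { ok <- FALSE }
      }
      if (ok) chains[[length(chains) + 1L]] <- idx
    }
  }
  # keep inclusion-maximal chains only
  is_sub <- function(x, y) all(x %in% y)
  maximal <- Filter(function(ch) {
    !any(vapply(chains, function(other) {
      length(other) > length(ch) && is_sub(ch, other)
    }, logical(1)))
  }, chains)
  if (length(maximal) > 14) return(NULL)
  kmax <- max(lengths(maximal))
  labels <- vapply(doses, function(d) d$label, character(1))
  key_of <- function(sel) {
    paste(sort(vapply(maximal[sel], function(ch) {
      paste(labels[sort_chain(ch, rel)], collapse = "\r")
    }, character(1))), collapse = "\n")
  }
  best <- NULL; best_w <- Inf; best_key <- NULL
  for (mask in seq_len(2^length(maximal)) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_along(maximal) - 1)) > 0)
    if (length(sel) == 0) next
    if (!all(seq_len(n) %in% unlist(maximal[sel]))) next
    if (!any(lengths(maximal[sel]) == kmax)) next
    w <- sum(lengths(maximal[sel]))
    k <- key_of(sel)
    if (w < best_w || (w == best_w && k < best_key)) {
      best <- sel; best_w <- w; best_key <- k
    }
  }
  lapply(best, function(i) sort_chain(maximal[[i]], rel))
}

sort_chain <- function(idx, rel) {
  idx[order(vapply(idx, function(i) sum(rel[idx, i]), numeric(1)))]
}

# random small dose poset on a coarse two-agent grid (ties encouraged)
random_dose_poset <- function(n, two_agent = TRUE) {
  repeat {
    if (two_agent) {
      amts <- matrix(sample(c(10, 20, 30, 40), 2 * n, replace = TRUE), ncol = 2)
      keys <- paste(amts[, 1], amts[, 2])
      if (anyDuplicated(keys)) next
      return(lapply(seq_len(n), function(i) {
        dose_combination(c(A = amts[i, 1], B = amts[i, 2]),
                         label = sprintf("d%02d", i))
      }))
    } else {
      amts <- sample(seq(10, 100, by = 10), n)
      return(lapply(seq_len(n), function(i) {
        dose_combination(c(A = amts[i]), label = sprintf("d%02d", i))
      }))
    }
  }
}

# oracle: dense lattice maximiser of the Emax binomial log-likelihood
grid_search_loglik <- function(series, n_p = 25, n_e = 12, n_h = 12) {
  pts <- series$points
  kmax <- max(pts$level)
  g <- expand.grid(
    p_lo = seq(0.02, 0.98, length.out = n_p),
    p_hi = seq(0.02, 0.98, length.out = n_p),
    ed50 = seq(0.5, kmax + 1, length.out = n_e),
    hill = exp(seq(log(0.25), log(8), length.out = n_h))
  )
  ll <- rep(0, nrow(g))
  for (i in seq_len(nrow(pts))) {
    p <- g$p_lo + (g$p_hi - g$p_lo) *
      plogis(g$hill * (log(pts$level[i]) - log(g$ed50)))
    e <- pts$events[i]; nn <- pts$n[i]
    if (e > 0) ll <- ll + e * log(p)
    if (e < nn) ll <- ll + (nn - e) * log1p(-p)
  }
  list(max_loglik = max(ll), params = g[which.max(ll), ])
}

# deterministic binomial series drawn from known truth
simulate_series <- function(truth, k = 4, n_per_level = 100, seed = 1,
                            outcome = "DLT") {
  set.seed(seed)
  p <- emax_prob(truth, seq_len(k))
  analysis_series("sim", outcome, n = rep(n_per_level, k),
                  events = rbinom(k, n_per_level, p))
}
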