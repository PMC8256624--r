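#' A single administered dose, possibly a multi-agent combination
#'
#' Represents one dose as a map from agent name to a nonnegative amount
#' (units are free text and only assumed consistent within a study). Doses
#' of combination regimens are compared component-wise, which yields a
#' partial order: two doses can be incomparable when neither dominates the
#' other in every agent.
#'
#' @param components Named numeric vector of nonnegative, finite amounts;
#'   at least one agent.
#' @param label Optional display label; defaults to `"A=10; B=20"` style.
#' @return An object of class `dose_combination`.
#' @examples
#' d1 <- dose_combination(c(A = 10, B = 20))
#' d3 <- dose_combination(c(A = 20, B = 20))
#' compare_doses(d1, d3)
#' @export
dose_combination <- function(components, label = NULL) {
  if (!is.numeric(components) || length(components) == 0L) {
    stop("`components` must be a non-empty named numeric vector", call. = FALSE)
  }
  nms <- names(components)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop("`components` must have unique non-empty agent names", call. = FALSE)
  }
  if (any(!is.finite(components)) || any(components < 0)) {
    stop("agent amounts must be finite and >= 0", call. = FALSE)
  }
  components <- components[order(nms)]
  if (is.null(label)) {
    label <- paste(names(components), components, sep = "=", collapse = "; ")
  }
  structure(
    list(components = components, label = as.character(label)),
    class = "dose_combination"
  )
}

#' @export
print.dose_combination <- function(x, ...) {
  cat("<dose> ", x$label, "\n", sep = "")
  invisible(x)
}

#' @export
format.dose_combination <- function(x, ...) x$label

#' Compare two doses under the component-wise partial order
#'
#' Dose `a` is below dose `b` when, taking an absent agent as amount 0,
#' every agent's amount in `a` is at most its amount in `b`, with strict
#' inequality for at least one agent. When each dose exceeds the other in
#' some agent, the pair is incomparable — the situation that forces a
#' study's dose set to be split into separate analysis series.
#'
#' @param a,b [dose_combination] objects.
#' @return One of `"less"`, `"greater"`, `"equal"`, `"incomparable"`.
#' @export
compare_doses <- function(a, b) {
  stopifnot(inherits(a, "dose_combination"), inherits(b, "dose_combination"))
  agents <- union(names(a$components), names(b$components))
  va <- ifelse(agents %in% names(a$components), a$components[agents], 0)
  vb <- ifelse(agents %in% names(b$components), b$components[agents], 0)
  if (all(va == vb)) return("equal")
  if (all(va <= vb)) return("less")
  if (all(va >= vb)) return("greater")
  "incomparable"
}

#' Decompose a dose set into fully orderable analysis series
#'
#' Splits a (possibly partially ordered) set of doses into chains — subsets
#' on which every pair is comparable and strictly ascending — following the
#' series-formation rules used throughout the package:
#'
#' * every emitted chain is a *maximal* chain of the dose poset (it cannot
#'   be extended by any further dose), so each series is as long as the
#'   order structure allows;
#' * every dose is covered by at least one chain (no outcome data are
#'   discarded);
#' * a dose is allocated to more than one chain only when repetition is the
#'   only way to avoid an orphan dose, i.e. a series of size one;
#' * among valid covers, total dose repetition is minimised, with remaining
#'   ties broken by lexicographic order of the dose labels, so the output
#'   is deterministic.
#'
#' A fully ordered input therefore comes back as a single chain, while the
#' classic two-agent crossed pair (`A=10;B=20` vs `A=20;B=10`, both below
#' `A=20;B=20`) yields two chains of size two sharing the top dose.
#'
#' @param doses List of [dose_combination] objects, pairwise distinct as
#'   agent-amount maps.
#' @return A list of chains; each chain is an integer vector of indices
#'   into `doses`, ordered ascending. Empty input gives an empty list.
#' @export
build_series <- function(doses) {
  if (length(doses) == 0L) return(list())
  stopifnot(all(vapply(doses, inherits, logical(1), "dose_combination")))
  n <- length(doses)
  cmp <- matrix("", n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) cmp[i, j] <- compare_doses(doses[[i]], doses[[j]])
  }
  if (any(cmp[upper.tri(cmp)] == "equal")) {
    stop("doses must be pairwise distinct as agent-amount maps", call. = FALSE)
  }
  less <- cmp == "less" # less[i, j]: dose i strictly below dose j
  chains <- maximal_chains(less)
  labels <- vapply(doses, function(d) d$label, character(1))
  select_chain_cover(chains, n, labels)
}

# All maximal chains of the strict partial order `less` (a logical matrix),
# each as an ascending integer vector. Grown by DFS from minimal elements
# along covering relations, so every returned chain is inclusion-maximal.
maximal_chains <- function(less) {
  n <- nrow(less)
  # Hasse covers: i -> j when i < j with nothing in between
  covers <- function(i) {
    above <- which(less[i, ])
    above[vapply(above, function(j) !any(less[i, ] & less[, j]), logical(1))]
  }
  minimal <- which(colSums(less) == 0)
  out <- list()
  grow <- function(chain) {
    nxt <- covers(chain[length(chain)])
    if (length(nxt) == 0L) {
      out[[length(out) + 1L]] <<- chain
    } else {
      for (j in nxt) grow(c(chain, j))
    }
  }
  for (i in minimal) grow(i)
  out
}

# Pick a cover of the dose set by maximal chains: must include at least one
# maximum-length chain; minimise total repetitions (= total length - n when
# all doses covered); tie-break lexicographically on the sorted sequence of
# chain label vectors. Exact branch-and-bound over chains per uncovered dose.
select_chain_cover <- function(chains, n, labels) {
  lens <- lengths(chains)
  # canonical chain order: by labels, for deterministic exploration/ties
  keys <- vapply(chains, function(ch) paste(labels[ch], collapse = "\r"), character(1))
  ord <- order(keys)
  chains <- chains[ord]
  lens <- lens[ord]
  keys <- keys[ord]
  kmax <- max(lens)

  membership <- lapply(seq_len(n), function(d) {
    which(vapply(chains, function(ch) d %in% ch, logical(1)))
  })

  best <- NULL
  best_weight <- Inf
  best_key <- NULL

  cover_key <- function(idx) paste(sort(keys[idx]), collapse = "\n")

  dfs <- function(chosen, covered, weight) {
    if (weight > best_weight) return()
    if (all(covered)) {
      key <- cover_key(chosen)
      if (weight < best_weight || (weight == best_weight && key < best_key)) {
        best <<- chosen
        best_weight <<- weight
        best_key <<- key
      }
      return()
    }
    # branch on the uncovered dose with fewest covering chains
    unc <- which(!covered)
    ncand <- lengths(membership[unc])
    d <- unc[which.min(ncand)]
    for (ci in membership[[d]]) {
      if (ci %in% chosen) next
      dfs(
        c(chosen, ci),
        covered | seq_len(n) %in% chains[[ci]],
        weight + lens[ci]
      )
    }
  }
  # a valid cover must contain a maximum-length chain: seed the search with
  # each one in turn, then cover the remaining doses exhaustively
  for (mi in which(lens == kmax)) {
    dfs(mi, seq_len(n) %in% chains[[mi]], lens[mi])
  }

  res <- chains[sort(best)]
  res[order(vapply(res, function(ch) paste(labels[ch], collapse = "\r"), character(1)))]
}

#' An analysis series: one orderable dose chain with outcome counts
#'
#' The unit of model fitting: a fully ordered run of dose levels from one
#' study, with the number of evaluable patients and the number of events
#' (DLT or OR) at each level. Levels are the ordinals 1..K along the chain;
#' the raw amounts are kept only as labels, since combination doses have no
#' common scalar scale. Series with a single dose level are retained but
#' flagged non-fittable: one dose cannot inform a dose-event gradient.
#'
#' @param study_id Study identifier.
#' @param outcome `"DLT"` or `"OR"`.
#' @param n Positive integer patient counts per level.
#' @param events Nonnegative event counts per level, `events <= n`.
#' @param dose_labels Optional character labels per level.
#' @param series_id Optional identifier; defaults to `study_id`.
#' @return An object of class `analysis_series` with a `points` tibble
#'   (`level`, `dose_label`, `n`, `events`) and a `fittable` flag.
#' @export
analysis_series <- function(study_id, outcome, n, events,
                            dose_labels = NULL, series_id = NULL) {
  outcome <- match.arg(outcome, c("DLT", "OR"))
  k <- length(n)
  if (k == 0L) stop("series must contain at least one dose level", call. = FALSE)
  if (length(events) != k) stop("`n` and `events` lengths differ", call. = FALSE)
  if (any(n <= 0) || any(n != round(n))) {
    stop("patient counts must be positive integers", call. = FALSE)
  }
  if (any(events < 0) || any(events != round(events)) || any(events > n)) {
    stop("event counts must be integers in [0, n]", call. = FALSE)
  }
  if (is.null(dose_labels)) dose_labels <- as.character(seq_len(k))
  if (is.null(series_id)) series_id <- as.character(study_id)
  structure(
    list(
      study_id = as.character(study_id),
      series_id = as.character(series_id),
      outcome = outcome,
      points = tibble::tibble(
        level = seq_len(k),
        dose_label = as.character(dose_labels),
        n = as.integer(n),
        events = as.integer(events)
      ),
      fittable = k >= 2L
    ),
    class = "analysis_series"
  )
}

#' @export
print.analysis_series <- function(x, ...) {
  cat(sprintf(
    "<analysis_series> %s [%s] study %s, %d level(s)%s\n",
    x$series_id, x$outcome, x$study_id, nrow(x$points),
    if (x$fittable) "" else " (not fittable)"
  ))
  print(x$points)
  invisible(x)
}

as_analysis_series <- function(x) {
  if (!inherits(x, "analysis_series")) {
    stop("expected an `analysis_series` object", call. = FALSE)
  }
  x
}

is_fittable <- function(series) isTRUE(series$fittable)

#' Build the analysis series of one study for one outcome
#'
#' Takes a study's dose-outcome records, keeps the doses with a reported
#' count for the requested outcome, decomposes those doses into fully
#' orderable chains with [build_series], and attaches the patient and event
#' counts to each chain with ordinal levels 1..K. Records with a missing
#' count for the requested outcome simply do not contribute a dose, so an
#' outcome reported at only a subset of a study's doses yields series over
#' that subset. Size-one chains come back flagged non-fittable.
#'
#' @param records Tibble of dose-outcome rows for **one** study, in the
#'   database schema of [read_database] (columns `study_id`, `dose_label`,
#'   `dose_components`, `n_evaluable_dlt`, `n_dlt`, `n_evaluable_or`,
#'   `n_or`).
#' @param outcome `"DLT"` or `"OR"`.
#' @return List of [analysis_series] (possibly empty). Series ids are
#'   `"<study_id>/<outcome>/<chain number>"`.
#' @export
make_analysis_series <- function(records, outcome = c("DLT", "OR")) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  sid <- unique(records$study_id)
  if (length(sid) != 1L) {
    stop("`records` must all come from a single study", call. = FALSE)
  }
  ncol_ <- if (outcome == "DLT") "n_evaluable_dlt" else "n_evaluable_or"
  ecol <- if (outcome == "DLT") "n_dlt" else "n_or"
  keep <- !is.na(records[[ncol_]]) & !is.na(records[[ecol]])
  recs <- records[keep, , drop = FALSE]
  if (nrow(recs) == 0L) return(list())
  doses <- lapply(seq_len(nrow(recs)), function(i) {
    dose_combination(parse_dose_components(recs$dose_components[i]),
                     label = recs$dose_label[i])
  })
  chains <- build_series(doses)
  lapply(seq_along(chains), function(ci) {
    idx <- chains[[ci]]
    analysis_series(
      study_id = sid,
      outcome = outcome,
      n = recs[[ncol_]][idx],
      events = recs[[ecol]][idx],
      dose_labels = recs$dose_label[idx],
      series_id = paste(sid, outcome, ci, sep = "/")
    )
  })
}
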