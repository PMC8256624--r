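#' Tabulate curve heights of fitted series with study metadata
#'
#' One row per fitted series: the posterior-mean height and central
#' interval for Bayesian fits, or the point height for converged
#' maximum-likelihood fits, joined to the study's grouping metadata
#' (treatment class, disease, design class). Failed maximum-likelihood fits
#' are dropped with their failure reason recorded in the `failure` column
#' of the attribute `"failed"`; a fit whose study is absent from the
#' database is an error naming the offending series.
#'
#' @param fits List of `emax_mle_fit` / `emax_bayes_fit` objects (each
#'   carries its series and study identity).
#' @param db The [dose_db] the series came from.
#' @return A tibble of height records: `study_id`, `series_id`, `outcome`,
#'   `method`, `height_mean`, `interval_lo`, `interval_hi`,
#'   `treatment_class`, `disease`, `design_class`.
#' @export
height_table <- function(fits, db) {
  stopifnot(is.list(fits), inherits(db, "dose_db"))
  ids <- vapply(fits, function(f) f$study_id, character(1))
  unmatched <- setdiff(unique(ids), db$studies$study_id)
  if (length(unmatched)) {
    stop("fits reference unknown studies: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  failed <- list()
  for (f in fits) {
    method <- if (inherits(f, "emax_bayes_fit")) "bayes" else "mle"
    if (method == "mle" && !f$converged) {
      failed[[length(failed) + 1L]] <- tibble::tibble(
        series_id = f$series_id, failure = f$failure_reason
      )
      next
    }
    h <- height_of_fit(f)
    meta <- db$studies[db$studies$study_id == f$study_id, ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      study_id = f$study_id, series_id = f$series_id, outcome = f$outcome,
      method = method, height_mean = h$mean,
      interval_lo = if (method == "bayes") h$lower else NA_real_,
      interval_hi = if (method == "bayes") h$upper else NA_real_,
      treatment_class = meta$treatment_class, disease = meta$disease,
      design_class = meta$design_class
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failed") <- dplyr::bind_rows(failed)
  out
}

#' Summarise curve heights by a grouping variable
#'
#' Per group and outcome: number of series, mean height, and the share of
#' series with a positive mean height — the statistic behind the headline
#' contrast that most dose-toxicity curves rise with dose while
#' dose-response curves straddle zero.
#'
#' @param records Height records from [height_table] (>= 1 row).
#' @param group_by Name of a grouping column (e.g. `"treatment_class"`,
#'   `"disease"`, `"design_class"`, or `"outcome"`).
#' @return A tibble with `group`, `outcome`, `n`, `mean_height`,
#'   `share_positive`.
#' @export
grouped_height_summary <- function(records, group_by = "treatment_class") {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (!group_by %in% names(records)) {
    stop("unknown grouping field: ", group_by, call. = FALSE)
  }
  records |>
    dplyr::group_by(group = .data[[group_by]], .data$outcome) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_height = mean(.data$height_mean),
      share_positive = mean(.data$height_mean > 0),
      .groups = "drop"
    )
}

# presentation transform: centralise levels at zero and keep at most the
# middle nine; for K > 9 the kept levels are ceil((K-9)/2) + 1 .. + 9
centralised_levels <- function(levels) {
  k <- length(levels)
  keep <- if (k > 9) {
    off <- ceiling((k - 9) / 2)
    seq(off + 1, off + 9)
  } else {
    seq_len(k)
  }
  list(keep = keep, centred = levels[keep] - mean(levels))
}

#' Panel plot of fitted dose-event curves by treatment class
#'
#' Draws each fitted series' event-probability curve over its dose levels
#' centralised at zero (the series' mean level subtracted), truncated to
#' the middle nine levels when a series spans more, one panel per treatment
#' class. Figures are presentation artifacts; numerical checks belong to
#' the underlying tables.
#'
#' @param fits List of fit objects (failed ML fits are skipped).
#' @param db The [dose_db].
#' @param outcome `"DLT"` or `"OR"`; only fits for that outcome are drawn.
#' @param file Optional output path (png/pdf/svg); when given the plot is
#'   also written with `ggplot2::ggsave()`.
#' @return The ggplot object, invisibly when `file` is given.
#' @export
plot_curve_panels <- function(fits, db, outcome = c("DLT", "OR"), file = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(is.list(fits), inherits(db, "dose_db"))
  rows <- list()
  for (f in fits) {
    if (f$outcome != outcome) next
    if (inherits(f, "emax_mle_fit") && !f$converged) next
    cl <- centralised_levels(f$levels)
    fc <- fitted_curve(f, levels = f$levels[cl$keep])
    meta <- db$studies[db$studies$study_id == f$study_id, ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      series_id = f$series_id, treatment_class = meta$treatment_class,
      x = cl$centred, prob = fc$prob
    )
  }
  dat <- dplyr::bind_rows(rows)
  if (nrow(dat) == 0L) stop("no drawable fits for outcome ", outcome, call. = FALSE)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$prob,
                                         group = .data$series_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~treatment_class) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Dose-level (centralised at zero)",
      y = sprintf("Fitted probability of %s", outcome)
    ) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Dot plot of curve heights by treatment class
#'
#' Curve heights with their intervals, DLT and OR side by side within each
#' treatment class, against a dashed red reference line at zero height (no
#' dose-event relationship). Heights outside \[-1, 1\] are a validation
#' error: no probability difference can exceed 1 in magnitude.
#'
#' @param records Height records from [height_table].
#' @param file Optional output path; written with `ggplot2::ggsave()`.
#' @return The ggplot object, invisibly when `file` is given.
#' @export
plot_height_dots <- function(records, file = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (any(abs(records$height_mean) > 1)) {
    stop("height_mean outside [-1, 1]: invalid records", call. = FALSE)
  }
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$outcome,
                                             y = .data$height_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::facet_wrap(~treatment_class) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "Curve height (p at top dose - p at bottom dose)") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}
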