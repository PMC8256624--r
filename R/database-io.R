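#' @importFrom rlang .data
NULL

db_schema_cols <- c(
  "study_id", "year", "design_class", "disease_class", "disease",
  "treatment_class", "contains_chemotherapy", "dose_label",
  "dose_components", "n_evaluable_dlt", "n_dlt", "n_evaluable_or", "n_or"
)

design_classes <- c("rule_based", "model_based")
disease_classes <- c("haematological", "non_haematological", "both", "undisclosed")

# "A=10; B=20" -> named numeric c(A = 10, B = 20)
parse_dose_components <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) {
    stop("empty dose_components field", call. = FALSE)
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    stop("malformed dose_components: ", s, call. = FALSE)
  }
  amounts <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2L)))
  names(amounts) <- trimws(vapply(kv, `[`, character(1), 1L))
  if (any(is.na(amounts))) stop("non-numeric amount in: ", s, call. = FALSE)
  amounts
}

format_dose_components <- function(components) {
  components <- components[order(names(components))]
  paste(names(components), components, sep = "=", collapse = "; ")
}

#' Construct and validate a dose-outcome database
#'
#' The database couples one row of study metadata per trial with one row per
#' study-dose of outcome counts. Validation enforces the core invariants:
#' events never exceed evaluable patients, each record carries at least one
#' outcome pair (a row with neither a DLT nor an OR count conveys nothing),
#' every record's `study_id` resolves to exactly one metadata row, years are
#' plausible, and the design/disease classes take their enumerated values.
#' Missing outcome counts are `NA`, never 0: zero events is information,
#' absence of reporting is not.
#'
#' @param studies Tibble with columns `study_id`, `year`, `design_class`
#'   (`"rule_based"`/`"model_based"`), `disease_class` (`"haematological"`,
#'   `"non_haematological"`, `"both"`, `"undisclosed"`), `disease`,
#'   `treatment_class`, `contains_chemotherapy` (logical).
#' @param records Tibble with columns `study_id`, `dose_label`,
#'   `dose_components` (semicolon-separated `agent=amount` pairs),
#'   `n_evaluable_dlt`, `n_dlt`, `n_evaluable_or`, `n_or`; an optional
#'   `series_id` column marks pre-formed analysis series.
#' @return An object of class `dose_db`.
#' @export
dose_db <- function(studies, records) {
  studies <- tibble::as_tibble(studies)
  records <- tibble::as_tibble(records)
  problems <- character(0)

  need_s <- c("study_id", "year", "design_class", "disease_class", "disease",
              "treatment_class", "contains_chemotherapy")
  miss <- setdiff(need_s, names(studies))
  if (length(miss)) {
    stop("studies table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  need_r <- setdiff(db_schema_cols, need_s[-1])
  miss <- setdiff(need_r, names(records))
  if (length(miss)) {
    stop("records table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  if (anyDuplicated(studies$study_id)) {
    problems <- c(problems, "duplicated study_id in studies table")
  }
  bad <- which(!(studies$year >= 1990 & studies$year <= 2030))
  if (length(bad)) {
    problems <- c(problems, paste0("study row ", bad, ": year outside [1990, 2030]"))
  }
  bad <- which(!studies$design_class %in% design_classes)
  if (length(bad)) {
    problems <- c(problems, paste0("study row ", bad, ": unknown design_class"))
  }
  bad <- which(!studies$disease_class %in% disease_classes)
  if (length(bad)) {
    problems <- c(problems, paste0("study row ", bad, ": unknown disease_class"))
  }

  bad <- which(!records$study_id %in% studies$study_id)
  if (length(bad)) {
    problems <- c(problems, paste0("record row ", bad, ": study_id not in studies table"))
  }
  has_dlt <- !is.na(records$n_evaluable_dlt) & !is.na(records$n_dlt)
  has_or <- !is.na(records$n_evaluable_or) & !is.na(records$n_or)
  bad <- which(!(has_dlt | has_or))
  if (length(bad)) {
    problems <- c(problems, paste0("record row ", bad, ": neither DLT nor OR counts present"))
  }
  bad <- which(has_dlt & records$n_dlt > records$n_evaluable_dlt)
  if (length(bad)) {
    problems <- c(problems, paste0("record row ", bad, ": n_dlt exceeds n_evaluable_dlt"))
  }
  bad <- which(has_or & records$n_or > records$n_evaluable_or)
  if (length(bad)) {
    problems <- c(problems, paste0("record row ", bad, ": n_or exceeds n_evaluable_or"))
  }
  counts <- c("n_evaluable_dlt", "n_dlt", "n_evaluable_or", "n_or")
  for (cl in counts) {
    v <- records[[cl]]
    bad <- which(!is.na(v) & (v < 0 | v != round(v)))
    if (length(bad)) {
      problems <- c(problems, paste0("record row ", bad, ": ", cl, " not a nonnegative integer"))
    }
  }
  if (length(problems)) {
    stop("invalid database:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(list(studies = studies, records = records), class = "dose_db")
}

#' @export
print.dose_db <- function(x, ...) {
  cat(sprintf("<dose_db> %d studies, %d dose records\n",
              nrow(x$studies), nrow(x$records)))
  invisible(x)
}

#' Read a dose-outcome database from CSV or Excel
#'
#' The canonical interchange format is a flat UTF-8 CSV with one row per
#' study-dose and the columns `study_id, year, design_class, disease_class,
#' disease, treatment_class, contains_chemotherapy, dose_label,
#' dose_components, n_evaluable_dlt, n_dlt, n_evaluable_or, n_or` (plus an
#' optional `series_id`). Empty outcome cells are read as missing. The Excel
#' path maps the first sheet onto the same schema via readxl. Invariant
#' violations are collected and reported together in the error message,
#' naming the offending rows, rather than silently dropping them.
#'
#' @param path File to read.
#' @param format `"csv"` (default) or `"xlsx"`.
#' @return A validated [dose_db].
#' @export
read_database <- function(path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    flat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package", call. = FALSE)
    }
    flat <- readxl::read_excel(path)
  }
  miss <- setdiff(db_schema_cols, names(flat))
  if (length(miss)) {
    stop("schema mismatch: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  flat$contains_chemotherapy <- as.logical(flat$contains_chemotherapy)
  for (cl in c("n_evaluable_dlt", "n_dlt", "n_evaluable_or", "n_or", "year")) {
    flat[[cl]] <- suppressWarnings(as.numeric(flat[[cl]]))
  }
  studies <- dplyr::distinct(
    flat, .data$study_id, .data$year, .data$design_class, .data$disease_class,
    .data$disease, .data$treatment_class, .data$contains_chemotherapy
  )
  if (anyDuplicated(studies$study_id)) {
    stop("inconsistent study metadata across rows of the same study_id",
         call. = FALSE)
  }
  rec_cols <- c("study_id", "dose_label", "dose_components",
                "n_evaluable_dlt", "n_dlt", "n_evaluable_or", "n_or")
  if ("series_id" %in% names(flat)) rec_cols <- c(rec_cols, "series_id")
  dose_db(studies, flat[rec_cols])
}

#' Write a dose-outcome database to CSV
#'
#' Serialises a [dose_db] to the flat one-row-per-study-dose CSV schema of
#' [read_database]; `read_database(write_database(db))` returns an equal
#' database. Missing counts become empty cells.
#'
#' @param db A [dose_db].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "dose_db"))
  flat <- dplyr::left_join(db$records, db$studies, by = "study_id")
  extra <- intersect("series_id", names(flat))
  flat <- flat[, c(db_schema_cols, extra)]
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Build every analysis series in a database for one outcome
#'
#' Applies [make_analysis_series] study by study. When the records carry a
#' `series_id` column (pre-formed series, as a deposited dataset may store),
#' each group of rows sharing a non-missing `series_id` is taken as one
#' series in file order, validated as strictly ascending under the dose
#' partial order; rows with a missing `series_id` fall back to automatic
#' chain decomposition.
#'
#' @param db A [dose_db].
#' @param outcome `"DLT"` or `"OR"`.
#' @return List of [analysis_series].
#' @export
build_all_series <- function(db, outcome = c("DLT", "OR")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(db, "dose_db"))
  out <- list()
  for (sid in db$studies$study_id) {
    recs <- db$records[db$records$study_id == sid, , drop = FALSE]
    if (nrow(recs) == 0L) next
    if ("series_id" %in% names(recs) && any(!is.na(recs$series_id))) {
      pre <- recs[!is.na(recs$series_id), , drop = FALSE]
      for (gid in unique(pre$series_id)) {
        out <- c(out, preformed_series(pre[pre$series_id == gid, , drop = FALSE],
                                       outcome, gid))
      }
      recs <- recs[is.na(recs$series_id), , drop = FALSE]
      if (nrow(recs) == 0L) next
    }
    out <- c(out, make_analysis_series(recs, outcome))
  }
  out
}

preformed_series <- function(recs, outcome, gid) {
  ncol_ <- if (outcome == "DLT") "n_evaluable_dlt" else "n_evaluable_or"
  ecol <- if (outcome == "DLT") "n_dlt" else "n_or"
  keep <- !is.na(recs[[ncol_]]) & !is.na(recs[[ecol]])
  recs <- recs[keep, , drop = FALSE]
  if (nrow(recs) == 0L) return(list())
  doses <- lapply(recs$dose_components, function(s) {
    dose_combination(parse_dose_components(s))
  })
  if (nrow(recs) > 1L) {
    for (i in seq_len(nrow(recs) - 1L)) {
      if (compare_doses(doses[[i]], doses[[i + 1L]]) != "less") {
        stop("pre-formed series ", gid, " is not strictly ascending",
             call. = FALSE)
      }
    }
  }
  list(analysis_series(
    study_id = recs$study_id[1], outcome = outcome,
    n = recs[[ncol_]], events = recs[[ecol]],
    dose_labels = recs$dose_label,
    series_id = paste(recs$study_id[1], outcome, gid, sep = "/")
  ))
}

#' Characteristics summary of a database and its analysis series
#'
#' The descriptive table of the corpus: counts and within-column percentages
#' of manuscripts, DLT series, and OR series by year of publication,
#' experimental design class, disease class, disease label, treatment class,
#' and chemotherapy involvement, plus the median and interquartile range of
#' the number of dose-levels per series (type-7 linear-interpolation
#' quantiles, rendered `"4 (2, 5)"`). Empty inputs give a table of zeros.
#'
#' @param db A [dose_db].
#' @param series_dlt,series_or Lists of [analysis_series] built from `db`
#'   (e.g. via [build_all_series]).
#' @return A tibble with columns `block`, `category`, and count/percentage
#'   columns for manuscripts and each outcome; the dose-level row carries
#'   its `"median (q1, q3)"` rendering in `category`. The plain-text report
#'   is available through `format()`/`print()` of the returned object.
#' @export
characteristics_table <- function(db, series_dlt, series_or) {
  stopifnot(inherits(db, "dose_db"))
  s <- db$studies
  meta_of <- function(series_list) {
    if (length(series_list) == 0L) {
      return(s[0, , drop = FALSE])
    }
    ids <- vapply(series_list, function(x) x$study_id, character(1))
    s[match(ids, s$study_id), , drop = FALSE]
  }
  m_dlt <- meta_of(series_dlt)
  m_or <- meta_of(series_or)

  one_block <- function(block, field) {
    cats <- sort(unique(c(s[[field]], m_dlt[[field]], m_or[[field]])))
    if (length(cats) == 0L) return(NULL)
    cnt <- function(tab) {
      vapply(cats, function(cc) sum(tab[[field]] == cc), numeric(1),
             USE.NAMES = FALSE)
    }
    pct <- function(x) if (sum(x) > 0) 100 * x / sum(x) else rep(0, length(x))
    nm <- cnt(s); nd <- cnt(m_dlt); no <- cnt(m_or)
    tibble::tibble(
      block = block, category = as.character(cats),
      n_manuscripts = nm, pct_manuscripts = pct(nm),
      n_dlt_series = nd, pct_dlt_series = pct(nd),
      n_or_series = no, pct_or_series = pct(no)
    )
  }
  blocks <- list(
    one_block("Year of publication", "year"),
    one_block("Experimental design", "design_class"),
    one_block("Disease class", "disease_class"),
    one_block("Disease", "disease"),
    one_block("Treatment undergoing dose-escalation", "treatment_class"),
    one_block("Treatment ensemble contains chemotherapy", "contains_chemotherapy")
  )
  out <- dplyr::bind_rows(blocks)

  k_dlt <- vapply(series_dlt, function(x) nrow(x$points), numeric(1))
  k_or <- vapply(series_or, function(x) nrow(x$points), numeric(1))
  k_all <- c(k_dlt, k_or)
  lvl_row <- function(k, n_col, pct_col) {
    if (length(k) == 0L) return("0 (0, 0)")
    q <- stats::quantile(k, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sprintf("%g (%g, %g)", q[2], q[1], q[3])
  }
  out <- dplyr::bind_rows(out, tibble::tibble(
    block = "Number of dose-levels",
    category = lvl_row(k_all),
    n_manuscripts = NA_real_, pct_manuscripts = NA_real_,
    n_dlt_series = length(k_dlt), pct_dlt_series = NA_real_,
    n_or_series = length(k_or), pct_or_series = NA_real_
  ))
  attr(out, "totals") <- c(
    manuscripts = nrow(s), dlt_series = length(series_dlt),
    or_series = length(series_or)
  )
  class(out) <- c("characteristics_table", class(out))
  out
}

#' @export
format.characteristics_table <- function(x, ...) {
  tot <- attr(x, "totals")
  hdr <- sprintf("Manuscripts N = %d; DLT series N = %d; OR series N = %d",
                 tot["manuscripts"], tot["dlt_series"], tot["or_series"])
  lines <- hdr
  for (b in unique(x$block)) {
    lines <- c(lines, paste0("** ", b, " **"))
    rows <- x[x$block == b, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (b == "Number of dose-levels") {
        lines <- c(lines, sprintf("  median (IQR): %s", r$category))
      } else {
        lines <- c(lines, sprintf(
          "  %s: %g (%.0f%%) | DLT %g (%.0f%%) | OR %g (%.0f%%)",
          r$category, r$n_manuscripts, r$pct_manuscripts,
          r$n_dlt_series, r$pct_dlt_series, r$n_or_series, r$pct_or_series
        ))
      }
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
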