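#' Construct and validate a longitudinal validation table
#'
#' The validation data are observational and longitudinal: each subject is
#' observed at regular visits \eqn{k = 0, 1, \ldots} at which time-dependent
#' covariates \eqn{L_k} and the treatment indicator \eqn{A_k} are recorded,
#' while the event/censoring time is observed in continuous time. The table is
#' in long format, one row per subject-visit.
#'
#' Required logical columns (renamed internally to canonical names):
#' subject id, visit index, treatment indicator (0/1), event time
#' \eqn{T^* = \min(T, C) \ge 0} and event indicator \eqn{D \in \{0, 1\}}.
#' Time-dependent covariate columns (`l_cols`) and baseline prognostic columns
#' (`p_cols`) are declared by name.
#'
#' Invariants enforced: every subject has a visit-0 row; visits are consecutive
#' integers from 0; the last visit satisfies \eqn{k_{max} \le \lfloor T^*
#' \rfloor}; event time and indicator are constant within subject; baseline
#' columns are constant within subject; no missing values in any declared
#' column. Event and censoring times are measured from the prediction origin
#' (time 0) and all subjects are untreated before time 0.
#'
#' @param data a data.frame in long format.
#' @param l_cols character vector of time-dependent covariate column names.
#' @param p_cols character vector of baseline prognostic column names.
#' @param id,visit,treatment,event_time,event_indicator names of the columns
#'   holding the respective fields in `data`.
#' @return an object of class `cf_longitudinal`: a data.frame with canonical
#'   columns `id`, `visit`, `A`, `event_time`, `event_indicator` plus the
#'   declared covariate columns, sorted by (id, visit), with attributes
#'   `l_cols` and `p_cols`.
#' @seealso [read_longitudinal()], [apply_artificial_censoring()]
#' @export
longitudinal_table <- function(data, l_cols = character(), p_cols = character(),
                               id = "id", visit = "visit", treatment = "A",
                               event_time = "event_time",
                               event_indicator = "event_indicator") {
  stopifnot(is.data.frame(data))
  mapped <- c(id = id, visit = visit, A = treatment,
              event_time = event_time, event_indicator = event_indicator)
  missing_cols <- setdiff(unname(c(mapped, l_cols, p_cols)), names(data))
  if (length(missing_cols))
    abort_fmt("missing column(s): %s", paste(missing_cols, collapse = ", "))

  out <- data.frame(id = data[[id]], visit = data[[visit]], A = data[[treatment]],
                    event_time = data[[event_time]],
                    event_indicator = data[[event_indicator]],
                    data[, c(l_cols, p_cols), drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(out$id, out$visit), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "l_cols") <- l_cols
  attr(out, "p_cols") <- p_cols
  class(out) <- c("cf_longitudinal", "data.frame")
  validate_longitudinal(out)
  out
}

#' @rdname longitudinal_table
#' @param table a `cf_longitudinal` object (or a data.frame with the canonical
#'   columns) to validate.
#' @export
validate_longitudinal <- function(table) {
  l_cols <- attr(table, "l_cols") %||% character()
  p_cols <- attr(table, "p_cols") %||% character()
  used <- c("id", "visit", "A", "event_time", "event_indicator", l_cols, p_cols)
  for (cl in used) {
    if (anyNA(table[[cl]]))
      abort_fmt("missing values in column '%s' (no imputation is performed)", cl)
  }
  if (!all(table$A %in% c(0, 1)))
    abort_fmt("treatment indicator must be 0/1")
  if (!all(table$event_indicator %in% c(0, 1)))
    abort_fmt("event indicator must be 0/1")
  if (any(table$event_time < 0))
    abort_fmt("event_time must be >= 0")
  if (any(table$visit != floor(table$visit) | table$visit < 0))
    abort_fmt("visit indices must be non-negative integers")

  sp <- split(seq_len(nrow(table)), table$id)
  for (sid in names(sp)) {
    rows <- sp[[sid]]
    ks <- table$visit[rows]
    if (ks[1L] != 0)
      abort_fmt("subject %s: missing visit-0 row", sid)
    if (!identical(as.numeric(ks), as.numeric(seq_along(ks) - 1)))
      abort_fmt("subject %s: non-consecutive visits", sid)
    tt <- table$event_time[rows]
    dd <- table$event_indicator[rows]
    if (length(unique(tt)) > 1L || length(unique(dd)) > 1L)
      abort_fmt("subject %s: event_time/event_indicator not constant within subject", sid)
    if (max(ks) > floor(tt[1L]))
      abort_fmt("subject %s: visit after end of follow-up (k_max %d > floor(T*) %d)",
                sid, max(ks), floor(tt[1L]))
    for (pc in p_cols) {
      if (length(unique(table[[pc]][rows])) > 1L)
        abort_fmt("subject %s: baseline column '%s' not constant within subject", sid, pc)
    }
  }
  invisible(table)
}

#' Read or write a long-format longitudinal table
#'
#' The file format is delimited text (CSV) with a header. The mapping from
#' file columns to the logical fields, and the lists of time-dependent (`L`)
#' and baseline (`P`) covariate columns, are given by a schema: a named list
#' with entries `id`, `visit`, `treatment`, `event_time`, `event_indicator`
#' (each a column name, with sensible defaults) and `l_cols`, `p_cols`
#' (character vectors). A schema can be read from YAML with [read_schema()].
#'
#' @param path path to a CSV file.
#' @param schema a schema list, or a path to a YAML schema file.
#' @return a validated `cf_longitudinal` table.
#' @export
read_longitudinal <- function(path, schema = list()) {
  if (is.character(schema)) schema <- read_schema(schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  longitudinal_table(raw,
                     l_cols = schema$l_cols %||% character(),
                     p_cols = schema$p_cols %||% character(),
                     id = schema$id %||% "id",
                     visit = schema$visit %||% "visit",
                     treatment = schema$treatment %||% "A",
                     event_time = schema$event_time %||% "event_time",
                     event_indicator = schema$event_indicator %||% "event_indicator")
}

#' @rdname read_longitudinal
#' @param table a `cf_longitudinal` table.
#' @export
write_longitudinal <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_longitudinal
#' @export
read_schema <- function(path) {
  sc <- yaml::read_yaml(path)
  sc$l_cols <- as.character(sc$l_cols %||% character())
  sc$p_cols <- as.character(sc$p_cols %||% character())
  sc
}

#' Read a predictions table
#'
#' One estimated risk \eqn{\hat R^{a}(\tau | X)} per (subject, strategy,
#' horizon): columns `id`, `strategy`, `horizon`, `risk`, risks in \[0, 1\].
#'
#' @param path path to a CSV file with columns id, strategy, horizon, risk.
#' @return a data.frame of class `cf_predictions`.
#' @export
read_predictions <- function(path) {
  pr <- utils::read.csv(path, stringsAsFactors = FALSE)
  predictions_table(pr)
}

#' @rdname read_predictions
#' @param data a data.frame with columns id, strategy, horizon, risk.
#' @export
predictions_table <- function(data) {
  need <- c("id", "strategy", "horizon", "risk")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    abort_fmt("predictions table missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (any(data$risk < 0 | data$risk > 1, na.rm = TRUE))
    abort_fmt("risks must lie in [0, 1]")
  if (anyNA(data$risk)) abort_fmt("missing values in risk column")
  class(data) <- c("cf_predictions", "data.frame")
  data
}

#' Attach predictions to a validation table
#'
#' Looks up the risk \eqn{\hat R^{a}(\tau | X_i)} for every subject in the
#' table, for one strategy label and one horizon. Every subject must have
#' exactly one matching prediction.
#'
#' @param table a `cf_longitudinal` table (or a `cf_censored` set).
#' @param preds a `cf_predictions` table.
#' @param strategy a `cf_strategy` object or a strategy label.
#' @param horizon the prediction horizon \eqn{\tau}.
#' @return a named numeric vector of risks, one per subject, in subject order.
#' @export
align_predictions <- function(table, preds, strategy, horizon) {
  label <- if (inherits(strategy, "cf_strategy")) strategy$label else as.character(strategy)
  ids <- subject_ids(table)
  sel <- preds[preds$strategy == label & preds$horizon == horizon, , drop = FALSE]
  if (anyDuplicated(sel$id)) {
    dup <- unique(sel$id[duplicated(sel$id)])
    abort_fmt("duplicate prediction for subject(s) %s (strategy '%s', horizon %s)",
              paste(dup, collapse = ", "), label, format(horizon))
  }
  m <- match(ids, sel$id)
  if (anyNA(m)) {
    miss <- ids[is.na(m)]
    abort_fmt("missing prediction for subject(s) %s (strategy '%s', horizon %s)",
              paste(miss, collapse = ", "), label, format(horizon))
  }
  stats::setNames(sel$risk[m], ids)
}

#' Subject identifiers of a table, in canonical order
#'
#' @param x a `cf_longitudinal` table or a `cf_censored` set.
#' @return vector of unique subject ids.
#' @export
subject_ids <- function(x) {
  if (inherits(x, "cf_censored")) return(x$subjects$id)
  unique(x$id)
}
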