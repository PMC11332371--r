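# Inverse-probability-of-artificial-censoring weights.
#
# The weight at time t for a subject adherent to strategy a is
#   G_a^{-1}(t | L) = prod_{k=0}^{floor(t)} 1 / Pr(A_k = a_k | Abar_{k-1} = abar_{k-1}, Lbar_k),
# a right-continuous step function constant on [k, k+1). Its left-hand limit
# at integer t drops the factor at k = t. The combined weight multiplies in
# the inverse of the (covariate-free) standard-censoring survival function,
#   G_ac^{-1}(t | L) = G_a^{-1}(t | L) * G_c^{-1}(t).

# person-visit model frame for the treatment model: rows adherent through k-1,
# outcome y = I(A_k = a_k), with lag-1 L columns (visit-0 value carried at k=0)
treatment_model_frame <- function(table, strat) {
  cens <- if (inherits(table, "cf_censored")) table else
    apply_artificial_censoring(table, strat)
  tab <- cens$data
  s <- cens$subjects
  idx <- match(tab$id, s$id)
  keep <- tab$visit <= s$Ca[idx]          # adherent through k-1 (deviation row kept)
  fr <- as.data.frame(tab)[keep, , drop = FALSE]
  a_k <- strategy_actions(cens$strategy, fr$visit)
  fr$y_adh <- as.numeric(fr$A == a_k)
  l_cols <- attr(cens$data, "l_cols") %||% character()
  for (lc in l_cols) {
    lag <- c(NA, fr[[lc]][-nrow(fr)])
    lag[fr$visit == 0] <- fr[[lc]][fr$visit == 0]
    fr[[paste0(lc, "_lag1")]] <- lag
  }
  rownames(fr) <- NULL
  fr
}

#' Fit the pooled treatment (artificial-censoring) model
#'
#' Estimates \eqn{\Pr(A_k = a_k | \bar A_{k-1} = \bar a_{k-1}, \bar L_k)} by a
#' pooled discrete-time logistic regression across visits, fitted in the
#' validation data on the adherent risk set (subjects still consistent with
#' the strategy history through visit k-1; the visit at which a subject first
#' deviates contributes an outcome of 0). Visits at which the outcome is
#' constant (for instance continuation visits under an absorbing treatment)
#' are handled deterministically outside the regression.
#'
#' @param table a `cf_longitudinal` table (or an existing `cf_censored` set).
#' @param strat a `cf_strategy`.
#' @param formula optional one-sided formula for the linear predictor, built
#'   from `visit`, the L columns, their `_lag1` versions and the P columns;
#'   default: visit term plus all current L columns.
#' @param visit_term how the visit index enters the default specification:
#'   `"factor"` (one level per visit) or `"linear"`.
#' @param min_per_visit positivity diagnostic: a warning is raised for visits
#'   with fewer than this many deviations or adherences.
#' @return an object of class `cf_treatment_model` with elements `fit` (the
#'   glm, or NULL if fully deterministic), `deterministic` (named vector of
#'   per-visit probabilities handled outside the glm), `converged`,
#'   `per_visit` (counts of adherences/deviations per visit) and `degenerate`.
#' @export
fit_treatment_model <- function(table, strat, formula = NULL,
                                visit_term = c("factor", "linear"),
                                min_per_visit = 5) {
  visit_term <- match.arg(visit_term)
  fr <- treatment_model_frame(table, strat)
  l_cols <- attr(if (inherits(table, "cf_censored")) table$data else table,
                 "l_cols") %||% character()

  per_visit <- do.call(rbind, lapply(sort(unique(fr$visit)), function(k) {
    yk <- fr$y_adh[fr$visit == k]
    data.frame(visit = k, n = length(yk), n_adherent = sum(yk),
               n_deviating = sum(1 - yk))
  }))
  low <- per_visit$visit[pmin(per_visit$n_adherent, per_visit$n_deviating) < min_per_visit &
                           pmin(per_visit$n_adherent, per_visit$n_deviating) > 0]
  det_visits <- per_visit$visit[per_visit$n_adherent == 0 | per_visit$n_deviating == 0]

  deterministic <- numeric(0)
  for (k in det_visits) {
    yk <- fr$y_adh[fr$visit == k]
    if (all(yk == 1)) {
      deterministic[as.character(k)] <- 1
    } else {
      # every subject deviates at this visit: no adherent person-time remains
      warn_fmt("positivity: all subjects deviate at visit %d under strategy '%s'",
               k, strat$label)
      deterministic[as.character(k)] <- 0.5 / (length(yk) + 1)
    }
  }
  fit_rows <- fr[!(fr$visit %in% det_visits), , drop = FALSE]

  degenerate <- nrow(fit_rows) == 0L
  fit <- NULL
  converged <- TRUE
  if (degenerate) {
    if (all(fr$y_adh == 1))
      warn_fmt("all subjects adherent at every visit under strategy '%s'; adherence probabilities are degenerate (= 1)",
               strat$label)
  } else {
    rhs <- if (!is.null(formula)) {
      paste(deparse(formula[[2]]), collapse = "")
    } else {
      vt <- if (visit_term == "factor" && length(unique(fit_rows$visit)) > 1L)
        "factor(visit)" else "visit"
      paste(c(vt, l_cols), collapse = " + ")
    }
    f <- stats::as.formula(paste("y_adh ~", rhs))
    fit <- stats::glm(f, family = stats::binomial(), data = fit_rows)
    converged <- isTRUE(fit$converged)
    if (!converged)
      warn_fmt("treatment model did not converge (strategy '%s')", strat$label)
  }
  if (length(low))
    warn_fmt("positivity: fewer than %d deviations or adherences at visit(s) %s (strategy '%s')",
             min_per_visit, paste(low, collapse = ", "), strat$label)

  structure(list(fit = fit, deterministic = deterministic,
                 converged = converged, per_visit = per_visit,
                 degenerate = degenerate, strategy_label = strat$label,
                 l_cols = l_cols),
            class = "cf_treatment_model")
}

#' @rdname fit_treatment_model
#' @param object a `cf_treatment_model`.
#' @param newdata person-visit rows with the columns used in the fit.
#' @param ... unused.
#' @return `predict()`: fitted per-visit adherence probabilities.
#' @export
predict.cf_treatment_model <- function(object, newdata, ...) {
  p <- rep(NA_real_, nrow(newdata))
  det <- object$deterministic
  is_det <- as.character(newdata$visit) %in% names(det)
  if (any(is_det)) p[is_det] <- det[as.character(newdata$visit[is_det])]
  if (any(!is_det)) {
    if (is.null(object$fit))
      abort_fmt("treatment model is fully deterministic but prediction requested at visit(s) %s",
                paste(unique(newdata$visit[!is_det]), collapse = ", "))
    p[!is_det] <- stats::predict(object$fit, newdata = newdata[!is_det, , drop = FALSE],
                                 type = "response")
  }
  p
}

#' @export
print.cf_treatment_model <- function(x, ...) {
  cat(sprintf("<cf_treatment_model> strategy '%s', %s%s\n", x$strategy_label,
              if (x$degenerate) "degenerate (no deviations)" else
                sprintf("pooled logistic on %d person-visits", length(x$fit$y)),
              if (length(x$deterministic))
                sprintf("; deterministic visits: %s",
                        paste(names(x$deterministic), collapse = ", ")) else ""))
  invisible(x)
}

#' Compute inverse-probability-of-artificial-censoring weights
#'
#' Evaluates the fitted adherence probabilities \eqn{\hat p_k} for every
#' subject at each visit of their censored follow-up (visits
#' \eqn{k = 0, \ldots, \lfloor \tilde T \rfloor}) and forms the cumulative
#' product \eqn{\hat G_a^{-1}(t|L) = \prod_{k=0}^{\lfloor t \rfloor} 1 /
#' \hat p_k}, a per-subject step function.
#'
#' @param censored a `cf_censored` set.
#' @param model a `cf_treatment_model` fitted on the same validation data.
#' @param prob_floor positivity guard: a warning lists subjects with any
#'   fitted adherence probability below this floor (default 0.01). The
#'   probabilities are not modified.
#' @return a `cf_weights` table (see [weight_table()]).
#' @export
compute_ipacw <- function(censored, model, prob_floor = 0.01) {
  stopifnot(inherits(censored, "cf_censored"),
            inherits(model, "cf_treatment_model"))
  fr <- treatment_model_frame(censored, censored$strategy)
  s <- censored$subjects
  idx <- match(fr$id, s$id)
  keep <- fr$visit <= floor(s$T_tilde[idx])
  fr <- fr[keep, , drop = FALSE]

  p <- predict(model, fr)
  low <- p < prob_floor
  if (any(low))
    warn_fmt("positivity: fitted adherence probability below %g for subject(s) %s",
             prob_floor,
             paste(utils::head(unique(fr$id[low]), 10L), collapse = ", "))
  ip <- unsplit(lapply(split(1 / p, fr$id), cumprod), fr$id)
  weight_table(fr$id, fr$visit, ip, p_adh = p)
}

#' Construct a weight table
#'
#' Holds per-subject step-function weights on the visit grid: the value in
#' row (id, k) applies on \eqn{[k, k+1)}. Mostly produced by
#' [compute_ipacw()]; the constructor is exported so that hand-assigned
#' weights can be used for audits and worked examples. Weights must be
#' positive and non-decreasing in time within subject.
#'
#' @param id,visit,ipacw vectors of equal length: subject id, visit index and
#'   the artificial-censoring weight value on \eqn{[k, k+1)}.
#' @param p_adh optional fitted per-visit adherence probabilities.
#' @param gc optional `cf_gc` standard-censoring fit (see
#'   [fit_standard_censoring()]); usually attached later by
#'   [combine_weights()].
#' @return an object of class `cf_weights`.
#' @export
weight_table <- function(id, visit, ipacw, p_adh = NULL, gc = NULL) {
  df <- data.frame(id = id, visit = visit, ipacw = ipacw,
                   stringsAsFactors = FALSE)
  if (!is.null(p_adh)) df$p_adh <- p_adh
  df <- df[order(df$id, df$visit), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$ipacw <= 0)) abort_fmt("weights must be positive")
  dec <- unlist(lapply(split(df$ipacw, df$id), function(w) diff(w) < -1e-9))
  if (any(dec)) abort_fmt("weights must be non-decreasing in time within subject")
  attr(df, "gc") <- gc
  attr(df, "cap") <- NULL
  class(df) <- c("cf_weights", "data.frame")
  df
}

#' Estimate the standard-censoring survival function
#'
#' Standard (non-artificial) censoring is assumed not to depend on covariates;
#' \eqn{G_c(t) = \Pr(C > t)} is estimated by reverse Kaplan-Meier on the full
#' validation data, before artificial censoring (events are treated as
#' censorings and vice versa). If no standard censoring is present the
#' function is identically 1.
#'
#' @param table a `cf_longitudinal` table, or a `cf_censored` set, in which
#'   case artificial censoring is treated as ordinary censoring (reverse KM
#'   on \eqn{(\tilde T, \tilde D)}; this is what the naive subset comparator
#'   does).
#' @return an object of class `cf_gc` (a step function; evaluate with
#'   [gc_value()]).
#' @export
fit_standard_censoring <- function(table) {
  if (inherits(table, "cf_censored")) {
    tt <- table$subjects$T_tilde
    dd <- table$subjects$D_tilde
  } else {
    first_row <- !duplicated(table$id)
    tt <- table$event_time[first_row]
    dd <- table$event_indicator[first_row]
  }
  sf <- survival::survfit(survival::Surv(tt, 1 - dd) ~ 1)
  structure(list(time = sf$time, surv = sf$surv), class = "cf_gc")
}

#' @rdname fit_standard_censoring
#' @param gc a `cf_gc` object or NULL (treated as \eqn{G_c \equiv 1}).
#' @param t evaluation times.
#' @param left if TRUE, evaluate the left-hand limit \eqn{G_c(t-)}.
#' @export
gc_value <- function(gc, t, left = FALSE) {
  if (is.null(gc)) return(rep(1, length(t)))
  stopifnot(inherits(gc, "cf_gc"))
  pos <- if (left) findInterval(t, gc$time, left.open = TRUE)
  else findInterval(t, gc$time)
  c(1, gc$surv)[pos + 1L]
}

#' Combine artificial-censoring and standard-censoring weights
#'
#' Attaches the standard-censoring fit so that the combined weight
#' \eqn{G_{ac}^{-1}(t|L) = G_a^{-1}(t|L) \times G_c^{-1}(t)} can be evaluated,
#' optionally capping combined weights at a percentile of their values across
#' subject-visits (default: no truncation).
#'
#' @param ipacw a `cf_weights` table.
#' @param gc a `cf_gc` object (or NULL for no standard censoring).
#' @param truncation optional percentile in (0, 1]; combined weights are
#'   capped at this quantile of the combined values on the subject-visit grid.
#' @return the `cf_weights` table with the censoring component attached.
#' @export
combine_weights <- function(ipacw, gc = NULL, truncation = NULL) {
  stopifnot(inherits(ipacw, "cf_weights"))
  attr(ipacw, "gc") <- gc
  if (!is.null(truncation)) {
    stopifnot(truncation > 0, truncation <= 1)
    grid <- ipacw$ipacw / gc_value(gc, ipacw$visit)
    attr(ipacw, "cap") <- stats::quantile(grid, truncation, names = FALSE)
  } else {
    attr(ipacw, "cap") <- NULL
  }
  ipacw
}

#' Evaluate subject weights at arbitrary times
#'
#' Evaluates the per-subject weight step functions. The artificial-censoring
#' component at time t is the stored value at visit \eqn{\lfloor t \rfloor}
#' (carried forward past a subject's last recorded visit, where no further
#' treatment decisions occur); with `left = TRUE` and integer t the factor at
#' k = t is dropped (the left-hand limit used for case subjects in the
#' concordance weights).
#'
#' @param wt a `cf_weights` table.
#' @param ids subject ids (recycled against `t`).
#' @param t evaluation times.
#' @param component `"combined"` (default), `"ipacw"` or `"gc"`.
#' @param left evaluate left-hand limits.
#' @return numeric vector of weights.
#' @export
weight_at <- function(wt, ids, t, component = c("combined", "ipacw", "gc"),
                      left = FALSE) {
  component <- match.arg(component)
  n <- max(length(ids), length(t))
  ids <- rep_len(ids, n); t <- rep_len(t, n)
  k_eff <- floor(t)
  if (left) k_eff[t == k_eff] <- k_eff[t == k_eff] - 1

  ip <- rep(1, n)
  if (component %in% c("combined", "ipacw")) {
    sp <- split(seq_len(nrow(wt)), wt$id)
    for (q in seq_len(n)) {
      if (k_eff[q] < 0) next
      rows <- sp[[as.character(ids[q])]]
      if (is.null(rows))
        abort_fmt("no weights for subject %s", ids[q])
      pos <- findInterval(k_eff[q], wt$visit[rows])
      ip[q] <- if (pos == 0) 1 else wt$ipacw[rows[pos]]
    }
  }
  gcp <- rep(1, n)
  if (component %in% c("combined", "gc")) {
    g <- gc_value(attr(wt, "gc"), t, left = left)
    if (any(g <= 0))
      abort_fmt("standard-censoring survival estimate is zero at a requested time")
    gcp <- 1 / g
  }
  out <- ip * gcp
  cap <- attr(wt, "cap")
  if (!is.null(cap) && component == "combined") out <- pmin(out, cap)
  out
}

# n x (kmax+1) matrix of the ipacw component at integer times 0..kmax for the
# given subjects, carrying the last value forward; used by the metric kernels
ipacw_matrix <- function(wt, ids, kmax) {
  n <- length(ids)
  if (anyNA(match(ids, wt$id))) {
    miss <- setdiff(ids, wt$id)
    abort_fmt("no weights for subject(s) %s",
              paste(utils::head(miss, 5L), collapse = ", "))
  }
  m <- match(wt$id, ids)
  keep <- !is.na(m) & wt$visit <= kmax
  M <- matrix(NA_real_, n, kmax + 1L)
  M[cbind(m[keep], wt$visit[keep] + 1L)] <- wt$ipacw[keep]
  M[is.na(M[, 1L]), 1L] <- 1
  if (kmax > 0) {
    for (k in 2:(kmax + 1L)) {
      nas <- is.na(M[, k])
      if (any(nas)) M[nas, k] <- M[nas, k - 1L]
    }
  }
  M
}

# combined-weight evaluation via the matrix path: weight of subject row i at
# continuous time t (vectorised over pairs), used internally by the metrics
combined_at <- function(M, wt, row, t, left = FALSE) {
  k_eff <- floor(t)
  if (left) k_eff[t == k_eff] <- k_eff[t == k_eff] - 1
  ip <- ifelse(k_eff < 0, 1, M[cbind(row, pmax(k_eff, 0) + 1L)])
  g <- gc_value(attr(wt, "gc"), t, left = left)
  if (any(g <= 0))
    abort_fmt("standard-censoring survival estimate is zero at a requested time")
  out <- ip / g
  cap <- attr(wt, "cap")
  if (!is.null(cap)) out <- pmin(out, cap)
  out
}

#' Weight diagnostics
#'
#' Summaries used in validation reports: the distribution of the
#' artificial-censoring weights across subject-visits, and the weighted count
#' of subjects not artificially censored, which should be close to n at every
#' visit when the treatment model is correctly specified (a stabilization
#' diagnostic).
#'
#' @param censored a `cf_censored` set.
#' @param wt a `cf_weights` table.
#' @return a list with `weight_summary` (per-visit min/median/max/quantiles)
#'   and `adherent_weighted` (per-visit weighted adherent counts plus n).
#' @export
weight_diagnostics <- function(censored, wt) {
  ks <- sort(unique(wt$visit))
  ws <- do.call(rbind, lapply(ks, function(k) {
    v <- wt$ipacw[wt$visit == k]
    data.frame(visit = k, n = length(v), min = min(v),
               p50 = stats::median(v), p95 = stats::quantile(v, .95, names = FALSE),
               max = max(v))
  }))
  aw <- do.call(rbind, lapply(ks, function(k)
    data.frame(visit = k,
               weighted_count = adherent_weighted_count(censored, wt, k),
               n = nrow(censored$subjects))))
  list(weight_summary = ws, adherent_weighted = aw)
}

#' @rdname weight_diagnostics
#' @param k a visit index.
#' @return `adherent_weighted_count()`: the sum over subjects not artificially
#'   censored by the earlier of visit k and their end of follow-up of their
#'   weight \eqn{\hat G_a^{-1}} at that visit; its expectation is n under a
#'   correctly specified treatment model.
#' @export
adherent_weighted_count <- function(censored, wt, k) {
  s <- censored$subjects
  m <- pmin(k, floor(s$T_tilde))
  counted <- s$Ca > m
  if (!any(counted)) return(0)
  M <- ipacw_matrix(wt, s$id[counted], max(m))
  sum(M[cbind(seq_len(sum(counted)), m[counted] + 1L)])
}

#' Export a weight table for audit
#'
#' @param wt a `cf_weights` table.
#' @param path output CSV path.
#' @return the path, invisibly. Columns: id, visit, ipacw, gc_inv, combined.
#' @export
write_weights <- function(wt, path) {
  gc <- attr(wt, "gc")
  out <- as.data.frame(wt)
  out$gc_inv <- 1 / gc_value(gc, out$visit)
  out$combined <- out$ipacw * out$gc_inv
  cap <- attr(wt, "cap")
  if (!is.null(cap)) out$combined <- pmin(out$combined, cap)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
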