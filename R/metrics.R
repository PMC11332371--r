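# Counterfactual performance measures on the artificially censored set V_a.
#
# All estimators take the censored set, a weight table and a vector of
# predicted risks aligned to the subjects, and reduce to their standard
# unweighted analogues when everyone is adherent and uncensored.

# risks may be a named vector (matched by id) or positional
check_risks <- function(censored, risks) {
  s <- censored$subjects
  if (!is.null(names(risks))) {
    m <- match(as.character(s$id), names(risks))
    if (anyNA(m))
      abort_fmt("missing prediction for subject(s) %s",
                paste(utils::head(s$id[is.na(m)], 10L), collapse = ", "))
    risks <- unname(risks[m])
  }
  if (length(risks) != nrow(s))
    abort_fmt("expected %d risks, got %d", nrow(s), length(risks))
  if (any(risks < 0 | risks > 1)) abort_fmt("risks must lie in [0, 1]")
  risks
}

resolve_population <- function(censored, population) {
  s <- censored$subjects
  if (is.null(population)) return(seq_len(nrow(s)))
  m <- match(as.character(population), as.character(s$id))
  if (anyNA(m)) abort_fmt("population contains unknown subject ids")
  m
}

#' Weighted Kaplan-Meier estimate with time-varying weights
#'
#' Kaplan-Meier estimator in which each subject contributes their weight
#' evaluated at each event time, to both the risk set and the event count.
#' With the artificial-censoring weights this estimates the counterfactual
#' survival (and risk) had everyone followed the strategy.
#'
#' @param censored a `cf_censored` set.
#' @param wt a `cf_weights` table.
#' @param component which weight component to use: `"ipacw"` (default;
#'   standard covariate-free censoring is handled by the Kaplan-Meier risk
#'   sets themselves) or `"combined"`.
#' @param subset optional vector of subject ids to restrict to (used for
#'   grouped calibration).
#' @return an object of class `cf_km` with elements `time` and `surv`;
#'   evaluate risk with [km_risk()].
#' @export
weighted_km <- function(censored, wt, component = c("ipacw", "combined"),
                        subset = NULL) {
  component <- match.arg(component)
  s <- censored$subjects
  if (!is.null(subset)) s <- s[resolve_population(censored, subset), , drop = FALSE]
  tt <- s$T_tilde; dd <- s$D_tilde
  max_time <- if (nrow(s)) max(tt) else 0
  et <- sort(unique(tt[dd == 1]))
  et <- et[et > 0]
  if (!length(et)) {
    return(structure(list(time = numeric(0), surv = numeric(0),
                          max_time = max_time), class = "cf_km"))
  }
  kmax <- max(floor(tt))
  M <- ipacw_matrix(wt, s$id, kmax)
  gc <- if (component == "combined") attr(wt, "gc") else NULL
  gcv <- if (is.null(gc)) rep(1, length(et)) else gc_value(gc, et)
  surv <- numeric(length(et))
  S <- 1
  for (q in seq_along(et)) {
    te <- et[q]
    w <- M[, floor(te) + 1L] / gcv[q]
    at_risk <- tt >= te
    d <- sum(w[at_risk & tt == te & dd == 1])
    nw <- sum(w[at_risk])
    S <- S * (1 - d / nw)
    surv[q] <- S
  }
  structure(list(time = et, surv = surv, max_time = max_time),
            class = "cf_km")
}

#' @rdname weighted_km
#' @param km a `cf_km` object.
#' @param t evaluation time(s).
#' @return `km_risk()`: the estimated risk \eqn{1 - \hat S(t)}. Beyond the
#'   last observed follow-up time the last value is carried with a warning
#'   (the estimate is undefined there).
#' @export
km_risk <- function(km, t) {
  stopifnot(inherits(km, "cf_km"))
  if (any(t > km$max_time))
    warn_fmt("risk requested beyond the last observed follow-up time (%g); carrying the last estimate",
             km$max_time)
  if (!length(km$time)) return(rep(0, length(t)))
  pos <- findInterval(t, km$time)
  1 - c(1, km$surv)[pos + 1L]
}

#' @rdname weighted_km
#' @param t evaluation time.
#' @export
weighted_km_risk <- function(censored, wt, t, subset = NULL,
                             component = c("ipacw", "combined")) {
  km_risk(weighted_km(censored, wt, component = match.arg(component),
                      subset = subset), t)
}

#' Observed/expected ratio for counterfactual mean calibration
#'
#' The observed counterfactual outcome proportion by \eqn{\tau} (weighted
#' Kaplan-Meier on \eqn{V_a}) divided by the mean predicted risk
#' \eqn{\bar R^{a}(\tau) = \frac1n \sum_i \hat R^{a}(\tau | X_i)} over the
#' reference population (all n validation subjects by default).
#'
#' @param censored a `cf_censored` set.
#' @param wt a `cf_weights` table.
#' @param risks predicted risks (named by id or in subject order).
#' @param tau horizon.
#' @param component weight component for the Kaplan-Meier (see
#'   [weighted_km()]).
#' @param population optional subject ids over which the mean predicted risk
#'   is taken (the subset comparator restricts it).
#' @return the O/E ratio.
#' @export
oe_ratio <- function(censored, wt, risks, tau,
                     component = c("ipacw", "combined"), population = NULL) {
  risks <- check_risks(censored, risks)
  pop <- resolve_population(censored, population)
  expected <- mean(risks[pop])
  if (expected == 0) abort_fmt("mean predicted risk is zero; O/E undefined")
  observed <- weighted_km_risk(censored, wt, tau, component = match.arg(component))
  observed / expected
}

#' Grouped counterfactual calibration table
#'
#' Divides the predictions into G equal-sized groups by quantile (stable
#' ordering for ties), and compares the mean predicted risk per group with
#' the weighted Kaplan-Meier observed risk computed within the group in
#' \eqn{V_a}.
#'
#' @inheritParams oe_ratio
#' @param G number of groups (default 10).
#' @param population optional subject ids over which groups are formed (all
#'   subjects by default).
#' @return a data.frame with columns `group`, `n`, `mean_predicted`,
#'   `observed`, `n_adherent`; `observed` is NA (with a warning) for groups
#'   with no adherent person-time.
#' @export
calibration_by_group <- function(censored, wt, risks, tau, G = 10,
                                 component = c("ipacw", "combined"),
                                 population = NULL) {
  component <- match.arg(component)
  risks <- check_risks(censored, risks)
  pop <- resolve_population(censored, population)
  if (length(pop) < G)
    abort_fmt("need at least G = %d subjects to form groups, have %d", G, length(pop))
  r <- risks[pop]
  grp <- ceiling(rank(r, ties.method = "first") * G / length(pop))
  s <- censored$subjects
  out <- do.call(rbind, lapply(seq_len(G), function(g) {
    rows <- pop[grp == g]
    ids <- s$id[rows]
    adherent <- sum(s$T_tilde[rows] > 0)
    obs <- NA_real_
    if (adherent > 0) {
      obs <- tryCatch(weighted_km_risk(censored, wt, tau, subset = ids,
                                       component = component),
                      error = function(e) NA_real_)
    }
    data.frame(group = g, n = length(rows), mean_predicted = mean(r[grp == g]),
               observed = obs, n_adherent = adherent)
  }))
  if (anyNA(out$observed))
    warn_fmt("calibration group(s) %s have no adherent person-time; observed risk missing",
             paste(out$group[is.na(out$observed)], collapse = ", "))
  out
}

#' Counterfactual c-index truncated at a horizon
#'
#' Weighted concordance estimator over comparable pairs in \eqn{V_a}: pair
#' (i, j) is comparable when \eqn{\tilde T_i < \tilde T_j}, \eqn{\tilde T_i
#' \le \tau} and \eqn{\tilde D_i = 1}, and receives the weight
#' \eqn{\hat G_{ac}^{-1}(\tilde T_i- | L_i) \, \hat G_{ac}^{-1}(\tilde T_i |
#' L_j)} (left-hand limit for the case subject). The estimate is the weighted
#' proportion of comparable pairs in which the earlier-event subject received
#' the strictly higher predicted risk; prediction ties contribute 0 by
#' default, or 1/2 with `tie_credit = TRUE`.
#'
#' @inheritParams oe_ratio
#' @param tie_credit give prediction ties one-half credit instead of zero.
#' @return the concordance estimate, with attribute `n_comparable` (the
#'   unweighted number of comparable pairs).
#' @export
cf_cindex <- function(censored, wt, risks, tau, tie_credit = FALSE) {
  risks <- check_risks(censored, risks)
  s <- censored$subjects
  tt <- s$T_tilde; dd <- s$D_tilde; n <- nrow(s)
  case <- tt <= tau & dd == 1
  if (!any(case))
    abort_fmt("no comparable pairs by tau = %g: extended positivity requires a nonzero number of comparable pairs", tau)
  kmax <- max(floor(tt))
  M <- ipacw_matrix(wt, s$id, kmax)
  gc <- attr(wt, "gc")
  cap <- attr(wt, "cap")

  # case-subject factor (left limit); non-case rows are masked below, so
  # their values (possibly at times where G_c has run out) are neutralised
  wA <- numeric(n)
  wA[case] <- combined_at(M, wt, which(case), tt[case], left = TRUE)
  # control-subject factor at the case's event time: WB[i, j] = G^{-1}(T_i | L_j)
  kidx <- floor(tt) + 1L
  WB <- t(M[, kidx, drop = FALSE])                        # rows i, cols j
  gi <- gc_value(gc, tt)
  if (any(gi[case] <= 0))
    abort_fmt("standard-censoring survival estimate is zero at an event time")
  gi[!case] <- 1
  WB <- WB / gi
  if (!is.null(cap)) WB <- pmin(WB, cap)

  comp <- outer(tt, tt, "<")
  comp[!case, ] <- FALSE
  W <- (wA * comp) * WB
  den <- sum(W)
  if (den == 0)
    abort_fmt("no comparable pairs by tau = %g: extended positivity requires a nonzero number of comparable pairs", tau)
  conc <- outer(risks, risks, ">")
  num <- sum(W[conc & comp])
  if (tie_credit) {
    ties <- outer(risks, risks, "==")
    num <- num + 0.5 * sum(W[ties & comp])
  }
  structure(num / den, n_comparable = sum(comp))
}

#' Counterfactual cumulative/dynamic AUC at a horizon
#'
#' Cases are subjects with an observed event by t in \eqn{V_a}
#' (\eqn{\tilde T_i \le t, \tilde D_i = 1}); controls are subjects event-free
#' beyond t (\eqn{\tilde T_j > t}). The estimate is the weighted proportion
#' of case-control pairs in which the case received the strictly higher
#' predicted risk, with pair weight \eqn{\hat G_{ac}^{-1}(\tilde T_i- | L_i)
#' \, \hat G_{ac}^{-1}(t | L_j)}.
#'
#' @inheritParams cf_cindex
#' @param t evaluation horizon.
#' @return the AUC estimate, with attributes `n_cases` and `n_controls`.
#' @export
cf_auct <- function(censored, wt, risks, t, tie_credit = FALSE) {
  risks <- check_risks(censored, risks)
  s <- censored$subjects
  tt <- s$T_tilde; dd <- s$D_tilde; n <- nrow(s)
  case <- which(tt <= t & dd == 1)
  ctrl <- which(tt > t)
  if (!length(case)) abort_fmt("no cases by t = %g; AUC undefined", t)
  if (!length(ctrl)) abort_fmt("no controls beyond t = %g; AUC undefined", t)
  kmax <- max(floor(c(tt, t)))
  M <- ipacw_matrix(wt, s$id, kmax)
  w_case <- combined_at(M, wt, case, tt[case], left = TRUE)
  w_ctrl <- combined_at(M, wt, ctrl, rep(t, length(ctrl)), left = FALSE)
  conc <- outer(risks[case], risks[ctrl], ">")
  Wp <- outer(w_case, w_ctrl)
  num <- sum(Wp[conc])
  if (tie_credit) {
    ties <- outer(risks[case], risks[ctrl], "==")
    num <- num + 0.5 * sum(Wp[ties])
  }
  structure(num / sum(Wp), n_cases = length(case), n_controls = length(ctrl))
}

#' Counterfactual Brier score
#'
#' Weighted mean squared difference between the event indicator by t and the
#' predicted risk over all n validation subjects: observations with an event
#' by t contribute with weight \eqn{\hat G_{ac}^{-1}(\tilde T_i | L_i)},
#' observations event-free beyond t with weight \eqn{\hat G_{ac}^{-1}(t |
#' L_i)}, and observations censored before t contribute zero.
#'
#' @inheritParams oe_ratio
#' @param t evaluation horizon.
#' @return the Brier score estimate.
#' @export
cf_brier <- function(censored, wt, risks, t) {
  risks <- check_risks(censored, risks)
  s <- censored$subjects
  tt <- s$T_tilde; dd <- s$D_tilde; n <- nrow(s)
  kmax <- max(floor(c(tt, t)))
  M <- ipacw_matrix(wt, s$id, kmax)
  ev <- tt <= t & dd == 1
  surv <- tt > t
  W <- numeric(n)
  if (any(ev)) W[ev] <- combined_at(M, wt, which(ev), tt[ev])
  if (any(surv)) W[surv] <- combined_at(M, wt, which(surv), rep(t, sum(surv)))
  mean((as.numeric(tt <= t) - risks)^2 * W)
}

#' Scaled counterfactual Brier score
#'
#' \eqn{1 - BS(t) / BS_0(t)}, where the null-model score \eqn{BS_0(t)}
#' replaces every prediction by the counterfactual outcome proportion up to
#' t, estimated by the weighted proportion of event indicators in \eqn{V_a}
#' with the combined inverse-probability weights.
#'
#' @inheritParams cf_brier
#' @param bs optionally, a precomputed Brier score for the model predictions.
#' @return the scaled Brier score (1 = perfect; 0 = no better than the null
#'   model; negative = worse than the null model).
#' @export
scaled_brier <- function(censored, wt, risks, t, bs = NULL) {
  risks <- check_risks(censored, risks)
  if (is.null(bs)) bs <- cf_brier(censored, wt, risks, t)
  s <- censored$subjects
  tt <- s$T_tilde; dd <- s$D_tilde; n <- nrow(s)
  kmax <- max(floor(c(tt, t)))
  M <- ipacw_matrix(wt, s$id, kmax)
  ev <- tt <= t & dd == 1
  r0 <- if (any(ev)) sum(combined_at(M, wt, which(ev), tt[ev])) / n else 0
  r0 <- min(max(r0, 0), 1)
  bs0 <- cf_brier(censored, wt, rep(r0, n), t)
  if (bs0 == 0) abort_fmt("null-model Brier score is zero; scaled Brier undefined")
  1 - bs / bs0
}

#' Assemble a counterfactual metrics report
#'
#' Runs the full set of counterfactual performance measures at one horizon:
#' O/E ratio, grouped calibration, c-index, cumulative/dynamic AUC, Brier and
#' scaled Brier score.
#'
#' @inheritParams oe_ratio
#' @param G calibration groups.
#' @param tie_credit see [cf_cindex()].
#' @param km_component weight component for the calibration Kaplan-Meier.
#' @param population reference population for the mean predicted risk and the
#'   calibration groups (all subjects by default; the subset comparator
#'   restricts it to subjects entering \eqn{V_a} with positive follow-up).
#' @param label optional label stored in the report.
#' @return an object of class `cf_metrics_report`.
#' @export
cf_metrics <- function(censored, wt, risks, tau, G = 10, tie_credit = FALSE,
                       km_component = c("ipacw", "combined"),
                       population = NULL, label = NULL) {
  km_component <- match.arg(km_component)
  risks <- check_risks(censored, risks)
  pop <- resolve_population(censored, population)
  warnings_seen <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  observed <- wh(weighted_km_risk(censored, wt, tau, component = km_component))
  expected <- mean(risks[pop])
  calib <- wh(calibration_by_group(censored, wt, risks, tau, G = G,
                                   component = km_component, population = population))
  cidx <- wh(cf_cindex(censored, wt, risks, tau, tie_credit = tie_credit))
  auc <- wh(cf_auct(censored, wt, risks, tau, tie_credit = tie_credit))
  bs <- wh(cf_brier(censored, wt, risks, tau))
  sbs <- wh(scaled_brier(censored, wt, risks, tau, bs = bs))
  structure(list(
    strategy = label %||% censored$strategy$label, tau = tau,
    n = nrow(censored$subjects), n_population = length(pop),
    observed = observed, expected = expected,
    oe_ratio = if (expected > 0) observed / expected else NA_real_,
    calibration = calib,
    cindex = as.numeric(cidx), n_comparable = attr(cidx, "n_comparable"),
    auc = as.numeric(auc), brier = bs, scaled_brier = sbs,
    warnings = unique(warnings_seen)),
    class = "cf_metrics_report")
}

#' @export
print.cf_metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cf_metrics_report> strategy '%s', tau = %g, n = %d\n",
              x$strategy, x$tau, x$n))
  cat(sprintf("  O/E ratio      %s (observed %s, expected %s)\n",
              format(x$oe_ratio, digits = digits),
              format(x$observed, digits = digits),
              format(x$expected, digits = digits)))
  cat(sprintf("  C(tau)         %s  (%d comparable pairs)\n",
              format(x$cindex, digits = digits), x$n_comparable))
  cat(sprintf("  AUC(tau)       %s\n", format(x$auc, digits = digits)))
  cat(sprintf("  Brier          %s   scaled %s\n",
              format(x$brier, digits = digits),
              format(x$scaled_brier, digits = digits)))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Unit (all-ones) artificial-censoring weights
#'
#' A weight table with IPACW identically 1 on every subject's follow-up, with
#' an optional standard-censoring component. Used for the naive subset
#' comparator and for evaluating perfect counterfactual validation data.
#'
#' @param censored a `cf_censored` set.
#' @param gc optional `cf_gc` standard-censoring fit.
#' @return a `cf_weights` table.
#' @export
unit_weights <- function(censored, gc = NULL) {
  s <- censored$subjects
  ks <- lapply(floor(s$T_tilde), function(k) 0:k)
  wt <- weight_table(id = rep(s$id, lengths(ks)), visit = unlist(ks),
                     ipacw = 1)
  combine_weights(wt, gc = gc)
}

#' Naive subset-approach comparator
#'
#' Computes all performance measures on the artificially censored set without
#' the artificial-censoring weight component: predictions are compared with
#' the observed outcomes of the subjects who happened to follow the strategy,
#' with artificial censoring treated as if it were ordinary covariate-free
#' right censoring (the censoring weights are a reverse Kaplan-Meier on
#' \eqn{(\tilde T, \tilde D)}). Prone to selection bias under time-dependent
#' confounding, because the artificial censoring is in fact informative;
#' provided as the comparator.
#'
#' @param table a `cf_longitudinal` table.
#' @param risks predicted risks under the strategy (named by id or in subject
#'   order), or a `cf_predictions` table.
#' @param strat a `cf_strategy`.
#' @param tau horizon.
#' @param G,tie_credit,km_component passed to [cf_metrics()].
#' @return a `cf_metrics_report` (labelled as subset).
#' @export
subset_approach_metrics <- function(table, risks, strat, tau, G = 10,
                                    tie_credit = FALSE,
                                    km_component = c("ipacw", "combined")) {
  cens <- apply_artificial_censoring(table, strat)
  if (inherits(risks, "cf_predictions"))
    risks <- align_predictions(table, risks, strat, tau)
  gc <- fit_standard_censoring(cens)   # treats artificial censoring as ordinary
  wt <- unit_weights(cens, gc = gc)
  pop <- cens$subjects$id[cens$subjects$Ca > 0]
  cf_metrics(cens, wt, risks, tau, G = G, tie_credit = tie_credit,
             km_component = match.arg(km_component), population = pop,
             label = paste0(strat$label, " (subset)"))
}

#' Full counterfactual validation pipeline for one strategy
#'
#' Convenience wrapper: artificial censoring, treatment-model fitting,
#' weight computation, standard-censoring estimation and the metrics report.
#'
#' @inheritParams subset_approach_metrics
#' @param formula optional treatment-model formula (see
#'   [fit_treatment_model()]).
#' @param truncation optional weight-truncation percentile (see
#'   [combine_weights()]).
#' @param prob_floor positivity floor for [compute_ipacw()].
#' @return a `cf_metrics_report` with the weight table attached as attribute
#'   `weights` and the censored set as attribute `censored`.
#' @export
counterfactual_metrics <- function(table, risks, strat, tau, G = 10,
                                   formula = NULL, truncation = NULL,
                                   tie_credit = FALSE, prob_floor = 0.01,
                                   km_component = c("ipacw", "combined")) {
  cens <- apply_artificial_censoring(table, strat)
  if (inherits(risks, "cf_predictions"))
    risks <- align_predictions(table, risks, strat, tau)
  tm <- fit_treatment_model(table, strat, formula = formula)
  wt <- compute_ipacw(cens, tm, prob_floor = prob_floor)
  gc <- fit_standard_censoring(table)
  wt <- combine_weights(wt, gc = gc, truncation = truncation)
  report <- cf_metrics(cens, wt, risks, tau, G = G, tie_credit = tie_credit,
                       km_component = match.arg(km_component))
  attr(report, "weights") <- wt
  attr(report, "censored") <- cens
  report
}

#' Calibration plot with diagonal reference
#'
#' @param x a `cf_metrics_report` or a calibration data.frame from
#'   [calibration_by_group()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_calibration <- function(x, ...) {
  calib <- if (inherits(x, "cf_metrics_report")) x$calibration else x
  lim <- range(0, calib$mean_predicted, calib$observed, na.rm = TRUE)
  graphics::plot(calib$mean_predicted, calib$observed, xlim = lim, ylim = lim,
                 xlab = "Mean predicted risk", ylab = "Observed risk (weighted KM)",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(calib)
}
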