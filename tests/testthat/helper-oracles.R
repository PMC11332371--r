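# Fixture builders and independent brute-force oracles.
#
# The oracles re-implement the estimators as plain double loops with their
# own step-function lookups, independent of the package's vectorised code
# paths, so agreement is a meaningful check.

# build a cf_longitudinal from per-subject specs:
# list(id=, A=c(...), L=c(...), P=, time=, event=)
make_table <- function(subjects) {
  rows <- do.call(rbind, lapply(subjects, function(s) {
    k <- seq_along(s$A) - 1
    data.frame(id = s$id, visit = k, A = s$A,
               L = if (length(s$L)) rep_len(s$L, length(k)) else 0,
               P = s$P %||% 0, event_time = s$time, event_indicator = s$event)
  }))
  longitudinal_table(rows, l_cols = "L", p_cols = "P")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain step-function weight lookup from a data.frame (id, visit, w)
oracle_ipacw <- function(wdf, id, t, left = FALSE) {
  k <- floor(t)
  if (left && t == k) k <- k - 1
  if (k < 0) return(1)
  rows <- wdf[wdf$id == id & wdf$visit <= k, , drop = FALSE]
  if (!nrow(rows)) return(1)
  rows$w[which.max(rows$visit)]
}

oracle_gc <- function(gcdf, t, left = FALSE) {
  if (is.null(gcdf)) return(1)
  keep <- if (left) gcdf$time < t else gcdf$time <= t
  if (!any(keep)) return(1)
  gcdf$surv[max(which(keep))]
}

# combined weight G_ac^{-1}(t | subject) from plain tables
make_wfun <- function(wdf, gcdf = NULL) {
  function(id, t, left = FALSE)
    oracle_ipacw(wdf, id, t, left) / oracle_gc(gcdf, t, left)
}

# explicit pair enumeration for the truncated concordance index
oracle_cindex <- function(tt, dd, r, ids, tau, wfun, tie_credit = FALSE) {
  num <- den <- 0
  n <- length(tt)
  for (i in seq_len(n)) {
    if (!(dd[i] == 1 && tt[i] <= tau)) next
    for (j in seq_len(n)) {
      if (!(tt[i] < tt[j])) next
      W <- wfun(ids[i], tt[i], left = TRUE) * wfun(ids[j], tt[i], left = FALSE)
      den <- den + W
      if (r[i] > r[j]) num <- num + W
      else if (tie_credit && r[i] == r[j]) num <- num + 0.5 * W
    }
  }
  num / den
}

oracle_auct <- function(tt, dd, r, ids, t, wfun, tie_credit = FALSE) {
  num <- den <- 0
  n <- length(tt)
  for (i in seq_len(n)) {
    if (!(dd[i] == 1 && tt[i] <= t)) next
    for (j in seq_len(n)) {
      if (!(tt[j] > t)) next
      W <- wfun(ids[i], tt[i], left = TRUE) * wfun(ids[j], t, left = FALSE)
      den <- den + W
      if (r[i] > r[j]) num <- num + W
      else if (tie_credit && r[i] == r[j]) num <- num + 0.5 * W
    }
  }
  num / den
}

# direct weighted sum for the Brier score
oracle_brier <- function(tt, dd, r, ids, t, wfun) {
  n <- length(tt)
  acc <- 0
  for (i in seq_len(n)) {
    W <- if (tt[i] <= t && dd[i] == 1) wfun(ids[i], tt[i])
    else if (tt[i] > t) wfun(ids[i], t)
    else 0
    acc <- acc + (as.numeric(tt[i] <= t) - r[i])^2 * W
  }
  acc / n
}

# weighted Kaplan-Meier risk by sequential event-time products
oracle_km_risk <- function(tt, dd, ids, t, wfun) {
  et <- sort(unique(tt[dd == 1 & tt > 0]))
  S <- 1
  for (te in et[et <= t]) {
    d <- nw <- 0
    for (i in seq_along(tt)) {
      if (tt[i] >= te) {
        w <- wfun(ids[i], te)
        nw <- nw + w
        if (tt[i] == te && dd[i] == 1) d <- d + w
      }
    }
    S <- S * (1 - d / nw)
  }
  1 - S
}

# treatment model stub with fixed per-visit adherence probabilities
make_det_model <- function(probs, label = "never") {
  structure(list(fit = NULL,
                 deterministic = stats::setNames(probs, seq_along(probs) - 1),
                 converged = TRUE, per_visit = NULL, degenerate = FALSE,
                 strategy_label = label, l_cols = character()),
            class = "cf_treatment_model")
}

make_gc <- function(time, surv) structure(list(time = time, surv = surv),
                                          class = "cf_gc")
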