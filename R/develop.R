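# Interventional prediction model development on simulated data.
#
# A marginal structural hazard model with inverse-probability-of-treatment
# weighting: a pooled logistic treatment model supplies stabilized weights,
# and a per-visit-interval hazard model in baseline predictors X = {L_0, P},
# current treatment and treatment duration is fitted on the weighted
# person-intervals. Duration matters because sustained treatment keeps
# lowering the time-dependent confounder, so the hazard under "always
# treated" drifts further from "never treated" the longer treatment lasts.
# Risks under a static strategy are obtained by accumulating the fitted
# hazard along the fixed treatment sequence. This is deliberately simple
# plumbing for the simulation study, not a general-purpose MSM fitter: the
# treatment process must be absorbing (once treated, always treated).

#' Develop an interventional prediction model on longitudinal data
#'
#' @param dev_table a `cf_longitudinal` development dataset with an absorbing
#'   treatment process.
#' @param family hazard family matching the generator: `"additive"`
#'   (per-interval hazard linear in covariates, fitted by weighted maximum
#'   likelihood) or `"proportional"` (log-linear, fitted by weighted Poisson
#'   regression on person-intervals).
#' @return an object of class `cf_devmodel`; obtain risks with
#'   `predict(model, newdata, strat, tau)` where `newdata` holds the baseline
#'   columns.
#' @export
develop_model <- function(dev_table, family = c("additive", "proportional")) {
  family <- match.arg(family)
  l_cols <- attr(dev_table, "l_cols") %||% character()
  p_cols <- attr(dev_table, "p_cols") %||% character()
  df <- as.data.frame(dev_table)

  a_prev <- c(0, df$A[-nrow(df)])
  a_prev[df$visit == 0] <- 0
  if (any(a_prev == 1 & df$A == 0))
    abort_fmt("develop_model requires an absorbing treatment process (no discontinuation)")

  # stabilized IPTW from pooled logistic models among the not-yet-treated
  pre <- a_prev == 0
  den_f <- stats::as.formula(paste("A ~ visit +", paste(l_cols, collapse = " + ")))
  fit_den <- stats::glm(den_f, stats::binomial(), data = df[pre, , drop = FALSE])
  fit_num <- stats::glm(A ~ visit, stats::binomial(), data = df[pre, , drop = FALSE])
  if (!fit_den$converged) warn_fmt("treatment-weight model did not converge")
  contrib <- rep(1, nrow(df))
  pd <- stats::predict(fit_den, newdata = df[pre, , drop = FALSE], type = "response")
  pn <- stats::predict(fit_num, newdata = df[pre, , drop = FALSE], type = "response")
  aa <- df$A[pre]
  contrib[pre] <- (pn^aa * (1 - pn)^(1 - aa)) / (pd^aa * (1 - pd)^(1 - aa))
  sw <- unsplit(lapply(split(contrib, df$id), cumprod), df$id)

  # person-interval data: interval [k, k+1) with exposure and event indicator
  first_row <- !duplicated(df$id)
  base <- df[first_row, c("id", l_cols, p_cols), drop = FALSE]
  names(base)[match(l_cols, names(base))] <- paste0(l_cols, "0")
  x_cols <- c(paste0(l_cols, "0"), p_cols)

  K <- max(df$visit) + 1L
  m <- match(df$id, base$id)
  dur <- stats::ave(df$A, df$id, FUN = cumsum) - df$A   # visits on treatment before k
  pi_df <- data.frame(visit = df$visit, A = df$A, dur = dur,
                      base[m, x_cols, drop = FALSE],
                      exposure = pmin(df$event_time, df$visit + 1) - df$visit,
                      y = df$event_indicator *
                        as.numeric(df$event_time < df$visit + 1),
                      sw = sw)
  pi_df <- pi_df[pi_df$exposure > 0, , drop = FALSE]

  p <- 3L + length(x_cols)  # intercept + baseline covariates + treatment + duration
  coefs <- matrix(NA_real_, K, p,
                  dimnames = list(NULL, c("(Intercept)", x_cols, "A", "dur")))
  for (k in 0:(K - 1L)) {
    dk <- pi_df[pi_df$visit == k, , drop = FALSE]
    X <- cbind(1, as.matrix(dk[, x_cols, drop = FALSE]), dk$A, dk$dur)
    # constant columns (duration at visit 0) are dropped; coefficient fixed at 0
    varying <- c(TRUE, apply(X[, -1L, drop = FALSE], 2, function(z) stats::var(z) > 0))
    X <- X[, varying, drop = FALSE]
    w <- dk$sw; e <- dk$exposure; y <- dk$y
    if (family == "additive") {
      nll <- function(g) {
        h <- drop(X %*% g)
        if (any(h <= 1e-10)) return(1e10)
        sum(w * (h * e - y * log(h)))
      }
      grad <- function(g) {
        h <- drop(X %*% g)
        if (any(h <= 1e-10)) return(rep(0, length(g)))
        drop(crossprod(X, w * (e - y / h)))
      }
      start <- c(sum(w * y) / sum(w * e), rep(0, ncol(X) - 1L))
      opt <- stats::nlminb(start, nll, gradient = grad)
      if (opt$convergence != 0 && opt$objective >= 1e10)
        warn_fmt("additive hazard fit failed to converge in interval %d", k)
      coefs[k + 1L, ] <- 0
      coefs[k + 1L, varying] <- opt$par
    } else {
      fit <- suppressWarnings(
        stats::glm.fit(X, dk$y, weights = w, offset = log(e),
                       family = stats::poisson()))
      if (!fit$converged)
        warn_fmt("proportional hazard fit failed to converge in interval %d", k)
      cc <- fit$coefficients
      cc[is.na(cc)] <- 0
      coefs[k + 1L, ] <- 0
      coefs[k + 1L, varying] <- cc
    }
  }
  structure(list(family = family, coefs = coefs, K = K, x_cols = x_cols,
                 l_cols = l_cols, p_cols = p_cols),
            class = "cf_devmodel")
}

#' @rdname develop_model
#' @param object a `cf_devmodel`.
#' @param newdata data.frame with one row per subject holding the baseline
#'   covariate columns (the L columns may carry their original names or a
#'   `0` suffix).
#' @param strat a `cf_strategy`.
#' @param tau horizon.
#' @param ... unused.
#' @return `predict()`: risks \eqn{\hat R^{a}(\tau | X)} in \[0, 1\].
#' @export
predict.cf_devmodel <- function(object, newdata, strat, tau, ...) {
  for (lc in object$l_cols) {
    l0 <- paste0(lc, "0")
    if (!l0 %in% names(newdata) && lc %in% names(newdata))
      newdata[[l0]] <- newdata[[lc]]
  }
  X <- cbind(1, as.matrix(newdata[, object$x_cols, drop = FALSE]))
  H <- numeric(nrow(newdata))
  dur <- 0
  for (k in 0:(object$K - 1L)) {
    len <- min(k + 1, tau) - k
    if (len <= 0) break
    g <- object$coefs[k + 1L, ]
    nx <- length(g)
    a_k <- strategy_actions(strat, k)
    eta <- drop(X %*% g[1:(nx - 2L)]) + g[nx - 1L] * a_k + g[nx] * dur
    h <- if (object$family == "additive") pmax(eta, 0) else exp(eta)
    H <- H + len * h
    dur <- dur + a_k
  }
  pmin(pmax(1 - exp(-H), 0), 1)
}

#' @export
print.cf_devmodel <- function(x, ...) {
  cat(sprintf("<cf_devmodel> %s hazard MSM, %d intervals, covariates: %s\n",
              x$family, x$K, paste(x$x_cols, collapse = ", ")))
  invisible(x)
}
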