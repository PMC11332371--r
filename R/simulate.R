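# Synthetic longitudinal data with time-dependent confounding.
#
# The generator emulates the standard confounded-treatment DAG: a baseline
# prognostic variable P (does not affect treatment), a time-dependent
# confounder L_k that predicts treatment initiation and the hazard and is
# itself lowered by past treatment, an absorbing treatment process A_k, and a
# continuous event time with a piecewise-constant hazard per visit interval
# (additive or proportional family). A matched "perfect" dataset in which
# everyone follows a given strategy is produced from the same underlying
# random draws (common random numbers), so that a fully adherent subject in
# the observational data has exactly the counterfactual event time of their
# perfect-data twin - consistency holds by construction.

#' Simulation scenario configuration
#'
#' Defaults define the reference study conditions: visits at integer times
#' 0..K-1 with administrative censoring at K, horizon `tau`, roughly half the
#' subjects initiating treatment by the horizon, material confounding, and an
#' additive hazard that is positive over the whole covariate support
#' (L is a truncated-normal autoregression on `L_bounds`, P is uniform on
#' \[0, 1\]).
#'
#' @param family hazard family: `"additive"` (h = beta0 + betaL L + betaA A +
#'   betaP P) or `"proportional"` (h = exp(g0 + gL L + gA A + gP P)).
#' @param n_dev,n_val development / validation sample sizes.
#' @param K number of visits (0..K-1); administrative censoring at time K.
#' @param tau prediction horizon.
#' @param beta0,betaL,betaA,betaP,betaU additive-hazard coefficients
#'   (intercept, time-dependent confounder, current treatment, baseline
#'   prognostic variable, hidden confounder).
#' @param g0,gL,gA,gP,gU log-hazard coefficients for the proportional family.
#' @param rho,thetaA,L_sd0,L_sd,L_bounds confounder process: \eqn{L_0 \sim
#'   TN(0, L_{sd0})}, \eqn{L_k \sim TN(\rho L_{k-1} + \theta_A A_{k-1},
#'   L_{sd})}, truncated to `L_bounds`.
#' @param alpha0,alphaL,alphaU treatment-initiation logistic model
#'   \eqn{\Pr(A_k = 1 | A_{k-1} = 0) = expit(\alpha_0 + \alpha_L L_k +
#'   \alpha_U U)}.
#' @param absorbing once treated, always treated (default TRUE).
#' @param censoring_rate exponential rate of standard (non-administrative)
#'   censoring; 0 disables it.
#' @param dev_baseline_multiplier multiplies the development-data baseline
#'   hazard only (the calibration-drift scenario uses 1.5).
#' @param measurement_error_sd SD of Gaussian error added to L_0 when
#'   computing predictions in the validation data (the error-prone-predictor
#'   scenario uses 1).
#' @param u_prob the hidden confounder U is Bernoulli(`u_prob`); it has an
#'   effect only when `alphaU` / `betaU` (or `gU`) are nonzero.
#' @return a list of class `cf_scenario_config`.
#' @export
scenario_config <- function(family = c("additive", "proportional"),
                            n_dev = 5000, n_val = 1000, K = 6, tau = 5,
                            beta0 = 0.12, betaL = 0.035, betaA = -0.04,
                            betaP = 0.08, betaU = 0,
                            g0 = log(0.13), gL = 0.25, gA = -0.35,
                            gP = 0.5, gU = 0,
                            rho = 0.8, thetaA = -0.5, L_sd0 = 1, L_sd = 0.6,
                            L_bounds = c(-2, 2),
                            alpha0 = -1.7, alphaL = 0.8, alphaU = 0,
                            absorbing = TRUE, censoring_rate = 0,
                            dev_baseline_multiplier = 1,
                            measurement_error_sd = 0, u_prob = 0.5) {
  cfg <- list(family = match.arg(family), n_dev = n_dev, n_val = n_val,
              K = K, tau = tau,
              beta0 = beta0, betaL = betaL, betaA = betaA, betaP = betaP,
              betaU = betaU, g0 = g0, gL = gL, gA = gA, gP = gP, gU = gU,
              rho = rho, thetaA = thetaA, L_sd0 = L_sd0, L_sd = L_sd,
              L_bounds = L_bounds, alpha0 = alpha0, alphaL = alphaL,
              alphaU = alphaU, absorbing = absorbing,
              censoring_rate = censoring_rate,
              dev_baseline_multiplier = dev_baseline_multiplier,
              measurement_error_sd = measurement_error_sd, u_prob = u_prob)
  class(cfg) <- c("cf_scenario_config", "list")
  check_hazard_positive(cfg)
  cfg
}

# additive hazards must be nonnegative over the covariate support
check_hazard_positive <- function(cfg, baseline_multiplier = 1) {
  if (cfg$family != "additive") return(invisible(TRUE))
  lo <- cfg$L_bounds[1]; hi <- cfg$L_bounds[2]
  h_min <- cfg$beta0 * baseline_multiplier +
    min(cfg$betaL * lo, cfg$betaL * hi) + min(0, cfg$betaA) +
    min(0, cfg$betaP) + min(0, cfg$betaU)
  if (h_min <= 0)
    abort_fmt("additive hazard can become non-positive (minimum %.4f) for coefficients beta0=%g, betaL=%g, betaA=%g, betaP=%g, betaU=%g over L in [%g, %g]",
              h_min, cfg$beta0 * baseline_multiplier, cfg$betaL, cfg$betaA,
              cfg$betaP, cfg$betaU, lo, hi)
  invisible(TRUE)
}

# all random draws for one dataset, in one fixed order; reused verbatim by
# the perfect-data generator so counterfactual twins share randomness
sim_draws <- function(cfg, n, seed) {
  set.seed(seed)
  list(uP = stats::runif(n),
       uL = matrix(stats::runif(n * cfg$K), n, cfg$K),
       uA = matrix(stats::runif(n * cfg$K), n, cfg$K),
       uU = stats::runif(n),
       uEvent = stats::runif(n),
       uCens = stats::runif(n),
       zErr = stats::rnorm(n))
}

interval_hazards <- function(cfg, L, A, P, U, baseline_multiplier = 1) {
  if (cfg$family == "additive") {
    cfg$beta0 * baseline_multiplier + cfg$betaL * L + cfg$betaA * A +
      cfg$betaP * P + cfg$betaU * U
  } else {
    baseline_multiplier * exp(cfg$g0 + cfg$gL * L + cfg$gA * A +
                                cfg$gP * P + cfg$gU * U)
  }
}

# core path generator; `actions` NULL for observational treatment assignment,
# or a cf_strategy whose sequence everyone follows
sim_paths <- function(cfg, draws, actions = NULL, baseline_multiplier = 1) {
  n <- length(draws$uP); K <- cfg$K
  lo <- cfg$L_bounds[1]; hi <- cfg$L_bounds[2]
  P <- draws$uP
  U <- as.numeric(draws$uU < cfg$u_prob)
  L <- matrix(NA_real_, n, K)
  A <- matrix(NA_real_, n, K)
  L[, 1] <- qtruncnorm(draws$uL[, 1], 0, cfg$L_sd0, lo, hi)
  for (k in seq_len(K)) {
    if (is.null(actions)) {
      p_init <- expit(cfg$alpha0 + cfg$alphaL * L[, k] + cfg$alphaU * U)
      new_trt <- as.numeric(draws$uA[, k] < p_init)
      A[, k] <- if (k == 1) new_trt else {
        if (cfg$absorbing) pmax(A[, k - 1], new_trt) else new_trt
      }
    } else {
      A[, k] <- strategy_actions(actions, k - 1)
    }
    if (k < K)
      L[, k + 1] <- qtruncnorm(draws$uL[, k + 1],
                               cfg$rho * L[, k] + cfg$thetaA * A[, k],
                               cfg$L_sd, lo, hi)
  }
  H <- matrix(NA_real_, n, K)
  for (k in seq_len(K))
    H[, k] <- interval_hazards(cfg, L[, k], A[, k], P, U, baseline_multiplier)
  cumH <- t(apply(H, 1, cumsum))
  E <- -log(draws$uEvent)
  Tev <- rep(Inf, n)
  prev <- 0
  for (k in seq_len(K)) {
    cp <- if (k == 1) rep(0, n) else cumH[, k - 1]
    hit <- is.infinite(Tev) & cumH[, k] >= E
    Tev[hit] <- (k - 1) + (E[hit] - cp[hit]) / H[hit, k]
  }
  Cc <- if (cfg$censoring_rate > 0) -log(draws$uCens) / cfg$censoring_rate else rep(Inf, n)
  Cc <- pmin(Cc, K)
  Tstar <- pmin(Tev, Cc)
  D <- as.numeric(Tev <= Cc)
  list(P = P, U = U, L = L, A = A, Tstar = Tstar, D = D, T_latent = Tev)
}

paths_to_table <- function(cfg, paths) {
  n <- length(paths$P)
  kmax <- pmin(cfg$K - 1, floor(paths$Tstar))
  nk <- kmax + 1L
  id <- rep(seq_len(n), nk)
  visit <- unlist(lapply(nk, function(m) 0:(m - 1L)))
  pick <- cbind(id, visit + 1L)
  df <- data.frame(id = id, visit = visit,
                   A = paths$A[pick], L = paths$L[pick],
                   P = paths$P[id],
                   event_time = paths$Tstar[id],
                   event_indicator = paths$D[id])
  longitudinal_table(df, l_cols = "L", p_cols = "P")
}

#' Simulate a confounded observational longitudinal dataset
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed; identical seeds reproduce identical tables, and
#'   [simulate_perfect()] with the same seed yields the matched counterfactual
#'   twin of every subject.
#' @param n number of subjects (default `cfg$n_val`).
#' @param baseline_multiplier multiplier on the baseline hazard (used for the
#'   development dataset in the calibration-drift scenario).
#' @return a `cf_longitudinal` table with columns L (time-dependent
#'   confounder) and P (baseline prognostic), plus attributes `latent`
#'   (uncensored event times) and `err_norm` (standard-normal draws for the
#'   error-prone baseline predictor).
#' @export
simulate_observational <- function(cfg, seed, n = cfg$n_val,
                                   baseline_multiplier = 1) {
  check_hazard_positive(cfg, baseline_multiplier)
  draws <- sim_draws(cfg, n, seed)
  paths <- sim_paths(cfg, draws, actions = NULL,
                     baseline_multiplier = baseline_multiplier)
  tab <- paths_to_table(cfg, paths)
  attr(tab, "latent") <- paths$T_latent
  attr(tab, "err_norm") <- draws$zErr
  tab
}

#' @rdname simulate_observational
#' @param strat a `cf_strategy` everyone follows.
#' @export
simulate_perfect <- function(cfg, strat, seed, n = cfg$n_val,
                             baseline_multiplier = 1) {
  check_hazard_positive(cfg, baseline_multiplier)
  draws <- sim_draws(cfg, n, seed)
  paths <- sim_paths(cfg, draws, actions = strat,
                     baseline_multiplier = baseline_multiplier)
  tab <- paths_to_table(cfg, paths)
  attr(tab, "latent") <- paths$T_latent
  tab
}

#' True counterfactual risk by Monte Carlo
#'
#' For given baseline values (L0, P), simulates forward paths of the
#' confounder process under the strategy and averages the conditional event
#' probability \eqn{1 - \exp(-H(\tau))} over paths. Serves as the generator's
#' ground truth for checking fitted prediction models.
#'
#' @param cfg a [scenario_config()].
#' @param strat a `cf_strategy`.
#' @param L0,P baseline values (vectors of equal length).
#' @param tau horizon.
#' @param nsim Monte Carlo paths per point.
#' @param seed RNG seed.
#' @return vector of risks, one per (L0, P) point.
#' @export
true_counterfactual_risk <- function(cfg, strat, L0, P, tau = cfg$tau,
                                     nsim = 5000, seed = 1) {
  stopifnot(length(L0) == length(P))
  set.seed(seed)
  lo <- cfg$L_bounds[1]; hi <- cfg$L_bounds[2]
  K <- cfg$K
  vapply(seq_along(L0), function(q) {
    L <- rep(L0[q], nsim)
    H <- numeric(nsim)
    for (k in 0:(K - 1)) {
      len <- min(k + 1, tau) - k
      if (len <= 0) break
      a_k <- strategy_actions(strat, k)
      H <- H + len * interval_hazards(cfg, L, a_k, P[q], 0)
      if (k < K - 1)
        L <- qtruncnorm(stats::runif(nsim), cfg$rho * L + cfg$thetaA * a_k,
                        cfg$L_sd, lo, hi)
    }
    mean(1 - exp(-H))
  }, numeric(1))
}
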