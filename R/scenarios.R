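# Scenario grid for verifying the counterfactual performance estimators.
#
# Per replicate: develop a prediction model on fresh development data, obtain
# predictions for a validation population, then evaluate them three ways -
# on perfect counterfactual validation data (truth), with the artificial
# censoring + IPACW estimators on the observational validation data, and
# with the naive subset approach - for both the never- and always-treated
# strategies.

VALID_SCENARIOS <- c("1", "2", "3", "exch", "pos", "wmisspec")

# scenario-specific modifications of the study conditions
scenario_setup <- function(scenario, cfg) {
  scenario <- as.character(scenario)
  if (!scenario %in% VALID_SCENARIOS)
    abort_fmt("unknown scenario '%s'; valid ids: %s", scenario,
              paste(VALID_SCENARIOS, collapse = ", "))
  dev_mult <- 1
  weight_formula <- NULL
  err_sd <- 0
  val_cfg <- cfg
  if (scenario == "2") {
    dev_mult <- if (cfg$dev_baseline_multiplier != 1) cfg$dev_baseline_multiplier else 1.5
  } else if (scenario == "3") {
    err_sd <- if (cfg$measurement_error_sd > 0) cfg$measurement_error_sd else 1
  } else if (scenario == "exch") {
    # hidden confounder affecting treatment and hazard, invisible to weights
    val_cfg$alphaU <- if (cfg$alphaU != 0) cfg$alphaU else 1
    if (cfg$family == "additive") {
      val_cfg$betaU <- if (cfg$betaU != 0) cfg$betaU else 0.04
    } else {
      val_cfg$gU <- if (cfg$gU != 0) cfg$gU else 0.3
    }
  } else if (scenario == "pos") {
    # steeper treatment assignment squeezes adherence probabilities to 0/1
    val_cfg$alphaL <- cfg$alphaL * 3
  } else if (scenario == "wmisspec") {
    weight_formula <- ~ visit   # omits the confounder from the weight model
  }
  list(dev_cfg = cfg, val_cfg = val_cfg, dev_mult = dev_mult,
       weight_formula = weight_formula, err_sd = err_sd)
}

metric_rows <- function(rep_id, strategy, approach, report) {
  calib <- report$calibration
  G <- nrow(calib)
  data.frame(rep = rep_id, strategy = strategy, approach = approach,
             metric = c("oe", "cindex", "auc", "brier", "scaled_brier",
                        "cal_low_gap", "cal_high_gap"),
             value = c(report$oe_ratio, report$cindex, report$auc,
                       report$brier, report$scaled_brier,
                       calib$observed[1] - calib$mean_predicted[1],
                       calib$observed[G] - calib$mean_predicted[G]),
             stringsAsFactors = FALSE)
}

#' Run a simulation scenario
#'
#' Scenarios: `"1"` development and validation data from the same model
#' (estimators should be unbiased); `"2"` development baseline hazard 1.5x
#' the validation one (calibration drift the estimators should detect);
#' `"3"` predictions computed from an error-prone baseline confounder
#' (discrimination loss and over-dispersed risks); `"exch"` hidden
#' confounder, `"pos"` positivity squeeze, `"wmisspec"` misspecified weight
#' model (assumption violations).
#'
#' @param scenario one of `"1"`, `"2"`, `"3"`, `"exch"`, `"pos"`,
#'   `"wmisspec"`.
#' @param reps number of replicates (>= 1).
#' @param cfg a [scenario_config()].
#' @param seed master seed; all replicate randomness derives from it.
#' @param G calibration groups per replicate.
#' @return an object of class `cf_scenario_result`: list with `results`
#'   (long data.frame: rep, strategy, approach, metric, value), `summary`
#'   (mean, Monte-Carlo SE and bias versus the perfect-data evaluation),
#'   `failures` (replicate ids and messages of non-fatal failures), and the
#'   scenario id.
#' @export
run_scenario <- function(scenario, reps, cfg = scenario_config(), seed = 1,
                         G = 10) {
  if (reps < 1) abort_fmt("reps must be >= 1")
  setup <- scenario_setup(scenario, cfg)
  strategies <- list(never = never_treated(), always = always_treated())

  set.seed(seed)
  dev_seeds <- sample.int(2147483646L, reps)
  val_seeds <- sample.int(2147483646L, reps)

  results <- vector("list", reps)
  failures <- list()
  for (r in seq_len(reps)) {
    res <- tryCatch(
      suppressWarnings(run_replicate(r, setup, strategies, dev_seeds[r],
                                     val_seeds[r], G = G)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, message = conditionMessage(res))
    } else {
      results[[r]] <- res
    }
  }
  results <- do.call(rbind, results)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(rep = integer(0), message = character(0))

  structure(list(scenario = as.character(scenario), reps = reps,
                 results = results, failures = failures,
                 summary = summarize_scenario(results), config = cfg),
            class = "cf_scenario_result")
}

run_replicate <- function(rep_id, setup, strategies, dev_seed, val_seed, G = 10) {
  dev_cfg <- setup$dev_cfg; val_cfg <- setup$val_cfg
  dev_tab <- simulate_observational(dev_cfg, dev_seed, n = dev_cfg$n_dev,
                                    baseline_multiplier = setup$dev_mult)
  model <- develop_model(dev_tab, family = dev_cfg$family)

  val_obs <- simulate_observational(val_cfg, val_seed, n = val_cfg$n_val)
  gc_obs <- fit_standard_censoring(val_obs)
  first <- !duplicated(val_obs$id)
  base <- data.frame(id = val_obs$id[first], L0 = val_obs$L[first],
                     P = val_obs$P[first])
  if (setup$err_sd > 0)
    base$L0 <- base$L0 + setup$err_sd * attr(val_obs, "err_norm")

  out <- list()
  for (nm in names(strategies)) {
    strat <- strategies[[nm]]
    risks <- stats::setNames(
      predict(model, data.frame(L0 = base$L0, P = base$P), strat, val_cfg$tau),
      base$id)

    perf_tab <- simulate_perfect(val_cfg, strat, val_seed, n = val_cfg$n_val)
    cens_p <- apply_artificial_censoring(perf_tab, strat)
    wt_p <- unit_weights(cens_p, gc = fit_standard_censoring(perf_tab))
    met_p <- cf_metrics(cens_p, wt_p, risks, val_cfg$tau, G = G)

    cens <- apply_artificial_censoring(val_obs, strat)
    tm <- fit_treatment_model(val_obs, strat, formula = setup$weight_formula)
    wt <- combine_weights(compute_ipacw(cens, tm), gc = gc_obs)
    met_cf <- cf_metrics(cens, wt, risks, val_cfg$tau, G = G)

    met_sub <- subset_approach_metrics(val_obs, risks, strat, val_cfg$tau, G = G)

    out[[nm]] <- rbind(metric_rows(rep_id, nm, "perfect", met_p),
                       metric_rows(rep_id, nm, "counterfactual", met_cf),
                       metric_rows(rep_id, nm, "subset", met_sub))
  }
  do.call(rbind, out)
}

summarize_scenario <- function(results) {
  if (is.null(results) || !nrow(results)) return(NULL)
  agg <- stats::aggregate(value ~ strategy + approach + metric, data = results,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              se = stats::sd(v, na.rm = TRUE) /
                                                sqrt(sum(!is.na(v)))))
  agg <- cbind(agg[, 1:3], as.data.frame(agg$value))
  perf <- agg[agg$approach == "perfect", c("strategy", "metric", "mean")]
  names(perf)[3] <- "perfect_mean"
  agg <- merge(agg, perf, by = c("strategy", "metric"), all.x = TRUE)
  agg$bias <- agg$mean - agg$perfect_mean
  agg[order(agg$metric, agg$strategy, agg$approach), ]
}

#' @export
print.cf_scenario_result <- function(x, ...) {
  cat(sprintf("<cf_scenario_result> scenario %s, %d replicates (%d failed)\n",
              x$scenario, x$reps, nrow(x$failures)))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
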