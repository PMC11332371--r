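# shared small fixture: fully adherent subjects, unit weights
adherent_fixture <- function(times, events, risks = NULL) {
  tab <- make_table(lapply(seq_along(times), function(i)
    list(id = i, A = rep(0, floor(times[i]) + 1), time = times[i],
         event = events[i])))
  cens <- apply_artificial_censoring(tab, never_treated())
  list(tab = tab, cens = cens, wt = unit_weights(cens))
}

test_that("weighted KM reduces to hand results and is scale invariant", {
  # all weights 1, n = 4, single event at t = 1: risk(2) = 0.25
  fx <- adherent_fixture(c(1, 3, 3.5, 4), c(1, 0, 0, 0))
  expect_equal(weighted_km_risk(fx$cens, fx$wt, 2), 0.25)

  # constant weights c: identical to unweighted KM
  s <- fx$cens$subjects
  ks <- lapply(floor(s$T_tilde), function(k) 0:k)
  wc <- weight_table(id = rep(s$id, lengths(ks)), visit = unlist(ks), ipacw = 3)
  expect_equal(weighted_km_risk(fx$cens, wc, 2), 0.25)

  # 3-subject fixture, event at t=1 by the weight-2 subject, others weight 1
  fx3 <- adherent_fixture(c(1, 2.5, 3), c(1, 0, 0))
  s3 <- fx3$cens$subjects
  ks3 <- lapply(floor(s3$T_tilde), function(k) 0:k)
  w3 <- weight_table(id = rep(s3$id, lengths(ks3)), visit = unlist(ks3),
                     ipacw = rep(c(2, 1, 1), lengths(ks3)))
  expect_equal(weighted_km_risk(fx3$cens, w3, 2), 0.5)

  # oracle agreement on the same fixture
  wdf <- data.frame(id = w3$id, visit = w3$visit, w = w3$ipacw)
  expect_equal(weighted_km_risk(fx3$cens, w3, 2),
               oracle_km_risk(s3$T_tilde, s3$D_tilde, s3$id, 2,
                              make_wfun(wdf)), tolerance = 1e-12)
})

test_that("beyond the last follow-up time the KM risk carries with a warning", {
  fx <- adherent_fixture(c(1, 2), c(1, 1))
  km <- weighted_km(fx$cens, fx$wt)
  expect_warning(r <- km_risk(km, 5), "beyond")
  expect_equal(r, 1)
})

test_that("O/E ratio behaves as a ratio of observed to mean predicted risk", {
  fx <- adherent_fixture(c(1, 3, 3.5, 4), c(1, 0, 0, 0))
  obs <- weighted_km_risk(fx$cens, fx$wt, 2)
  risks <- rep(obs, 4)
  expect_equal(oe_ratio(fx$cens, fx$wt, risks, 2), 1)
  expect_equal(oe_ratio(fx$cens, fx$wt, pmin(risks * 2, 1), 2), 0.5)
  expect_error(oe_ratio(fx$cens, fx$wt, rep(0, 4), 2), "zero")
})

test_that("grouped calibration reduces to mean calibration at G = 1 and handles ties", {
  fx <- adherent_fixture(seq(0.5, 5, length.out = 12), rep(c(1, 0), 6))
  risks <- seq(0.1, 0.9, length.out = 12)
  cal1 <- suppressWarnings(calibration_by_group(fx$cens, fx$wt, risks, 3, G = 1))
  expect_equal(cal1$observed, weighted_km_risk(fx$cens, fx$wt, 3))
  expect_equal(cal1$mean_predicted, mean(risks))

  # constant predictions: stable tie-break still gives equal-sized groups
  cal_t <- suppressWarnings(calibration_by_group(fx$cens, fx$wt, rep(0.4, 12), 3, G = 4))
  expect_equal(cal_t$n, rep(3, 4))
  expect_equal(cal_t$mean_predicted, rep(0.4, 4))
})

test_that("c-index handles perfect concordance and prediction ties", {
  fx <- adherent_fixture(c(1, 2, 3), c(1, 1, 1))
  # risks reversed against event times: earlier event, higher risk
  expect_equal(as.numeric(cf_cindex(fx$cens, fx$wt, c(0.9, 0.5, 0.1), 5)), 1)
  # identical risks: strict inequality gives 0; half credit with the flag
  expect_equal(as.numeric(cf_cindex(fx$cens, fx$wt, rep(0.5, 3), 5)), 0)
  expect_equal(as.numeric(cf_cindex(fx$cens, fx$wt, rep(0.5, 3), 5,
                                    tie_credit = TRUE)), 0.5)
  expect_error(cf_cindex(fx$cens, fx$wt, c(0.9, 0.5, 0.1), 0.5),
               "comparable pairs")
})

test_that("c-index and AUC equal brute-force pair enumeration on weighted fixtures", {
  # 6 subjects, two censorings, hand-assigned weights and a censoring fit
  tab <- make_table(list(
    list(id = 1, A = c(0, 0), time = 1.4, event = 1),
    list(id = 2, A = c(0, 0, 0), time = 2.2, event = 0),
    list(id = 3, A = c(0, 0, 0, 0), time = 3.6, event = 1),
    list(id = 4, A = c(0, 1), time = 4.1, event = 1),      # deviates at visit 1
    list(id = 5, A = c(0, 0, 0, 0, 0), time = 4.9, event = 0),
    list(id = 6, A = c(0, 0, 0, 0, 0, 0), time = 5.8, event = 1)))
  cens <- apply_artificial_censoring(tab, never_treated())
  s <- cens$subjects
  ks <- lapply(floor(s$T_tilde), function(k) 0:k)
  wvals <- c(1, 1.2, 1.5, 1.1, 2, 2.5)
  wdf <- data.frame(id = rep(s$id, lengths(ks)), visit = unlist(ks),
                    w = unlist(lapply(seq_along(ks), function(i)
                      seq(1, wvals[i], length.out = length(ks[[i]])))))
  gcdf <- data.frame(time = c(2.2, 4.9), surv = c(5 / 6, 5 / 6 * 0.75))
  wt <- combine_weights(weight_table(wdf$id, wdf$visit, wdf$w),
                        gc = make_gc(gcdf$time, gcdf$surv))
  wfun <- make_wfun(wdf, gcdf)
  risks <- c(0.7, 0.3, 0.55, 0.2, 0.4, 0.6)

  for (tau in c(3, 5)) {
    expect_equal(as.numeric(cf_cindex(cens, wt, risks, tau)),
                 oracle_cindex(s$T_tilde, s$D_tilde, risks, s$id, tau, wfun),
                 tolerance = 1e-12)
  }
  expect_equal(as.numeric(cf_auct(cens, wt, risks, 3)),
               oracle_auct(s$T_tilde, s$D_tilde, risks, s$id, 3, wfun),
               tolerance = 1e-12)
  expect_equal(cf_brier(cens, wt, risks, 3),
               oracle_brier(s$T_tilde, s$D_tilde, risks, s$id, 3, wfun),
               tolerance = 1e-12)
})

test_that("AUC separates perfectly separated risks and errors without cases or controls", {
  fx <- adherent_fixture(c(1, 1.5, 4, 4.5), c(1, 1, 0, 0))
  expect_equal(as.numeric(cf_auct(fx$cens, fx$wt, c(0.9, 0.8, 0.2, 0.1), 3)), 1)
  expect_error(cf_auct(fx$cens, fx$wt, c(0.9, 0.8, 0.2, 0.1), 0.5), "no cases")
  expect_error(cf_auct(fx$cens, fx$wt, c(0.9, 0.8, 0.2, 0.1), 10), "no controls")
})

test_that("AUC approaches one half for uninformative predictions", {
  cfg <- scenario_config()
  tab <- simulate_perfect(cfg, never_treated(), seed = 55, n = 2000)
  cens <- apply_artificial_censoring(tab, never_treated())
  wt <- unit_weights(cens, gc = fit_standard_censoring(tab))
  set.seed(99)
  risks <- runif(2000)
  expect_lt(abs(as.numeric(cf_auct(cens, wt, risks, 5)) - 0.5), 0.03)
  expect_lt(abs(as.numeric(cf_cindex(cens, wt, risks, 5)) - 0.5), 0.03)
})

test_that("Brier score reduces to mean squared error without censoring", {
  # deterministic outcomes predicted perfectly: BS = 0
  fx <- adherent_fixture(c(0.5, 0.7, 4, 4.5), c(1, 1, 1, 1))
  expect_equal(cf_brier(fx$cens, fx$wt, c(1, 1, 0, 0), 2), 0)

  # reduction to the plain MSE when no censoring of any kind
  risks <- c(0.3, 0.8, 0.2, 0.6)
  msE <- mean((as.numeric(fx$cens$subjects$T_tilde <= 2) - risks)^2)
  expect_equal(cf_brier(fx$cens, fx$wt, risks, 2), msE)

  # 5-subject fixture with one artificial censoring and hand weights
  tab <- make_table(list(
    list(id = 1, A = c(0, 0), time = 1.3, event = 1),
    list(id = 2, A = c(0, 1), time = 3, event = 1),    # censored at visit 1
    list(id = 3, A = c(0, 0, 0), time = 2.4, event = 1),
    list(id = 4, A = c(0, 0, 0, 0), time = 3.8, event = 0),
    list(id = 5, A = c(0, 0, 0, 0), time = 4.2, event = 1)))
  cens <- apply_artificial_censoring(tab, never_treated())
  s <- cens$subjects
  ks <- lapply(floor(s$T_tilde), function(k) 0:k)
  wdf <- data.frame(id = rep(s$id, lengths(ks)), visit = unlist(ks),
                    w = rep(c(1, 1.5, 1.25, 2, 1.1), lengths(ks)))
  wt <- combine_weights(weight_table(wdf$id, wdf$visit, wdf$w))
  risks5 <- c(0.9, 0.5, 0.7, 0.3, 0.4)
  hand <- ((1 - 0.9)^2 * 1 + (1 - 0.7)^2 * 1.25 + (0 - 0.3)^2 * 2 +
             (0 - 0.4)^2 * 1.1) / 5   # subject 2 censored before t: weight 0
  expect_equal(cf_brier(cens, wt, risks5, 3), hand, tolerance = 1e-12)
})

test_that("scaled Brier score hits its anchor points", {
  fx <- adherent_fixture(c(0.5, 0.7, 4, 4.5), c(1, 1, 1, 1))
  # null-model predictions give scaled BS exactly 0
  r0 <- mean(fx$cens$subjects$T_tilde <= 2)
  expect_equal(scaled_brier(fx$cens, fx$wt, rep(r0, 4), 2), 0)
  # perfect predictions give scaled BS 1
  expect_equal(scaled_brier(fx$cens, fx$wt, c(1, 1, 0, 0), 2), 1)
})

test_that("with full adherence and no censoring all metrics equal unweighted analogues", {
  cfg <- scenario_config()
  tab <- simulate_perfect(cfg, never_treated(), seed = 56, n = 300)
  cens <- apply_artificial_censoring(tab, never_treated())
  wt <- unit_weights(cens)
  s <- cens$subjects
  set.seed(7)
  risks <- plogis(s$id / 100 - 1.5 + rnorm(300, 0, 0.3))
  ones <- function(id, t, left = FALSE) 1

  expect_equal(as.numeric(cf_cindex(cens, wt, risks, 5)),
               oracle_cindex(s$T_tilde, s$D_tilde, risks, s$id, 5, ones),
               tolerance = 1e-12)
  expect_equal(as.numeric(cf_auct(cens, wt, risks, 5)),
               oracle_auct(s$T_tilde, s$D_tilde, risks, s$id, 5, ones),
               tolerance = 1e-12)
  expect_equal(cf_brier(cens, wt, risks, 5),
               oracle_brier(s$T_tilde, s$D_tilde, risks, s$id, 5, ones),
               tolerance = 1e-12)
  expect_equal(weighted_km_risk(cens, wt, 5),
               oracle_km_risk(s$T_tilde, s$D_tilde, s$id, 5, ones),
               tolerance = 1e-12)
})

test_that("reversing the prediction ranking maps C to 1 - C without ties", {
  cfg <- scenario_config()
  tab <- simulate_perfect(cfg, never_treated(), seed = 57, n = 200)
  cens <- apply_artificial_censoring(tab, never_treated())
  wt <- unit_weights(cens, gc = fit_standard_censoring(tab))
  set.seed(3)
  risks <- runif(200)
  c1 <- as.numeric(cf_cindex(cens, wt, risks, 5))
  c2 <- as.numeric(cf_cindex(cens, wt, 1 - risks, 5))
  expect_equal(c1 + c2, 1, tolerance = 1e-12)
  a1 <- as.numeric(cf_auct(cens, wt, risks, 5))
  a2 <- as.numeric(cf_auct(cens, wt, 1 - risks, 5))
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("overall KM risk aggregates group KM risks when nothing is censored", {
  fx <- adherent_fixture(seq(0.25, 2.75, by = 0.25), rep(1, 11))
  risks <- seq(0.05, 0.95, length.out = 11)
  cal <- suppressWarnings(calibration_by_group(fx$cens, fx$wt, risks, 2, G = 2))
  overall <- weighted_km_risk(fx$cens, fx$wt, 2)
  expect_equal(sum(cal$n * cal$observed) / sum(cal$n), overall, tolerance = 1e-12)
})

test_that("subset metrics match counterfactual metrics when treatment is unconfounded", {
  cfg <- scenario_config(alphaL = 0)   # treatment independent of L
  tab <- simulate_observational(cfg, seed = 58, n = 3000)
  first <- !duplicated(tab$id)
  risks <- stats::setNames(plogis(-0.3 + 0.6 * tab$L[first] + 0.5 * tab$P[first]),
                           tab$id[first])
  st <- never_treated()
  sub <- suppressWarnings(subset_approach_metrics(tab, risks, st, 5))
  cf <- suppressWarnings(counterfactual_metrics(tab, risks, st, 5))
  expect_lt(abs(sub$cindex - cf$cindex), 0.02)
  expect_lt(abs(sub$auc - cf$auc), 0.02)
  expect_lt(abs(sub$observed - cf$observed), 0.03)
})
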