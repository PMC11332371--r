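test_that("treatment model recovers an intercept-only assignment probability", {
  # treatment drawn independently of L with Pr(A_k = 1) = 0.3, non-absorbing
  cfg <- scenario_config(alpha0 = qlogis(0.3), alphaL = 0, absorbing = FALSE)
  tab <- simulate_observational(cfg, seed = 101, n = 5000)
  tm <- fit_treatment_model(tab, never_treated(), formula = ~ 1)
  p <- predict(tm, data.frame(visit = 0:4))
  # adherence to "never" means A_k = 0, probability 0.7
  expect_true(all(abs(p - 0.7) < 0.03))
})

test_that("treatment model recovers a known confounder coefficient", {
  cfg <- scenario_config(alpha0 = -1.2, alphaL = 0.8, absorbing = FALSE)
  tab <- simulate_observational(cfg, seed = 102, n = 5000)
  tm <- fit_treatment_model(tab, never_treated(), formula = ~ L)
  est <- stats::coef(summary(tm$fit))
  # adherence = 1 - initiation, so the L coefficient has flipped sign
  expect_lt(abs(est["L", "Estimate"] - (-0.8)), 2 * est["L", "Std. Error"])
})

test_that("full adherence yields degenerate probabilities with a warning", {
  tab <- make_table(lapply(1:6, function(i)
    list(id = i, A = c(0, 0, 0), time = 3.2, event = 1)))
  expect_warning(tm <- fit_treatment_model(tab, never_treated()),
                 "adherent at every visit")
  expect_true(tm$degenerate)
  cens <- apply_artificial_censoring(tab, never_treated())
  wt <- compute_ipacw(cens, tm)
  expect_true(all(wt$ipacw == 1))
})

test_that("IPACW are cumulative products of inverse adherence probabilities", {
  tab <- make_table(list(
    list(id = 1, A = c(0, 0, 0), time = 2.5, event = 1),
    list(id = 2, A = c(0, 0), time = 1.5, event = 0)))
  cens <- apply_artificial_censoring(tab, never_treated())
  tm <- make_det_model(c(0.8, 0.9, 0.5))
  wt <- compute_ipacw(cens, tm)

  # hand computation of the cumulative product
  expect_equal(weight_at(wt, 1, 1.5, "ipacw"), 1 / (0.8 * 0.9))
  expect_equal(weight_at(wt, 1, 2.3, "ipacw"), 1 / (0.8 * 0.9 * 0.5))
  # left limit at an integer drops the factor at k = t
  expect_equal(weight_at(wt, 1, 1, "ipacw", left = TRUE), 1 / 0.8)
  expect_equal(weight_at(wt, 1, 1, "ipacw"), 1 / (0.8 * 0.9))
  # non-integer times equal their own left limits
  expect_equal(weight_at(wt, 1, 1.5, "ipacw", left = TRUE),
               weight_at(wt, 1, 1.5, "ipacw"))
  # floor(0.5) = 0: single factor
  expect_equal(weight_at(wt, 2, 0.5, "ipacw"), 1 / 0.8)
})

test_that("a positivity floor violation is reported", {
  tab <- make_table(list(list(id = 1, A = c(0, 0), time = 1.5, event = 1)))
  cens <- apply_artificial_censoring(tab, never_treated())
  tm <- make_det_model(c(0.005, 0.9))
  expect_warning(compute_ipacw(cens, tm), "positivity.*below")
})

test_that("standard censoring is a reverse Kaplan-Meier", {
  # no censored subjects: G_c identically 1
  tab <- make_table(lapply(1:4, function(i)
    list(id = i, A = 0, time = i / 2, event = 1)))
  gc <- fit_standard_censoring(tab)
  expect_equal(gc_value(gc, c(0.5, 1, 5)), rep(1, 3))

  # n = 4, one censoring at t = 2, no earlier events
  tab2 <- make_table(list(
    list(id = 1, A = c(0, 0, 0), time = 2, event = 0),
    list(id = 2, A = c(0, 0, 0), time = 2.5, event = 1),
    list(id = 3, A = c(0, 0, 0, 0), time = 3.5, event = 1),
    list(id = 4, A = c(0, 0, 0, 0, 0), time = 4.5, event = 1)))
  gc2 <- fit_standard_censoring(tab2)
  expect_equal(gc_value(gc2, 1.9), 1)
  expect_equal(gc_value(gc2, c(2, 3, 4)), rep(0.75, 3))
  expect_equal(gc_value(gc2, 2, left = TRUE), 1)

  # administrative censoring of everyone at t = 5: G_c = 1 before 5
  tab3 <- make_table(lapply(1:5, function(i)
    list(id = i, A = rep(0, 5), time = 5, event = 0)))
  gc3 <- fit_standard_censoring(tab3)
  expect_equal(gc_value(gc3, c(1, 4.99)), c(1, 1))
})

test_that("combined weights multiply the two censoring components", {
  wt <- weight_table(id = c(1, 1), visit = c(0, 1), ipacw = c(1.25, 1.25))

  # gc = 1: combined equals ipacw
  w1 <- combine_weights(wt, gc = NULL)
  expect_equal(weight_at(w1, 1, 1.5), 1.25)

  # ipacw = 1, G_c(t) = 0.5 for t >= 2: combined = 2 there
  wu <- weight_table(id = c(1, 1, 1), visit = 0:2, ipacw = c(1, 1, 1))
  w2 <- combine_weights(wu, gc = make_gc(2, 0.5))
  expect_equal(weight_at(w2, 1, 1.5), 1)
  expect_equal(weight_at(w2, 1, 2.5), 2)

  # 1.25 x 1/0.8 = 1.5625
  w3 <- combine_weights(wt, gc = make_gc(1, 0.8))
  expect_equal(weight_at(w3, 1, 1.5), 1.5625)
})

test_that("weight truncation caps combined weights at the requested percentile", {
  wt <- weight_table(id = rep(1:5, each = 1), visit = rep(0, 5),
                     ipacw = c(1, 1, 1, 1, 100))
  wtr <- combine_weights(wt, gc = NULL, truncation = 0.8)
  expect_lt(weight_at(wtr, 5, 0.5), 100)
  expect_equal(weight_at(wtr, 1, 0.5), 1)
})

test_that("estimated IPACW are >= 1, non-decreasing, and match a brute-force product", {
  cfg <- scenario_config()
  tab <- simulate_observational(cfg, seed = 103, n = 300)
  cens <- apply_artificial_censoring(tab, never_treated())
  tm <- fit_treatment_model(tab, never_treated())
  wt <- compute_ipacw(cens, tm)

  expect_true(all(wt$ipacw >= 1))
  nondec <- tapply(wt$ipacw, wt$id, function(w) all(diff(w) >= -1e-12))
  expect_true(all(nondec))

  # oracle: per-subject product of per-visit reciprocals from the fitted p
  for (sid in unique(wt$id)[1:5]) {
    rows <- wt[wt$id == sid, ]
    expect_equal(rows$ipacw, cumprod(1 / rows$p_adh), tolerance = 1e-12)
  }
})

test_that("weighted adherent counts stay near n under a correct weight model", {
  cfg <- scenario_config()
  tab <- simulate_observational(cfg, seed = 104, n = 2000)
  for (st in list(never_treated(), always_treated())) {
    cens <- apply_artificial_censoring(tab, st)
    tm <- fit_treatment_model(tab, st)
    wt <- compute_ipacw(cens, tm)
    for (k in 0:(cfg$K - 1)) {
      expect_lt(abs(adherent_weighted_count(cens, wt, k) - 2000) / 2000, 0.05)
    }
  }
})
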