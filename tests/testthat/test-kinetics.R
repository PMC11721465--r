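test_that("plateau extraction matches the closed-form equilibrium", {
  p <- kinetic_params(1e5, 1e-2, 1)     # K_D = 100 nM, k_obs >= 0.016
  d <- assay_design(nM_series(), t_assoc = 600, t_dissoc = 60,
                    sample_rate = 5)    # 600 s >> 7/k_obs
  pl <- extract_plateau(simulate_1to1_sensorgram(p, d), window_s = 5)
  expect_equal(pl$concentration_M, sort(nM_series()))
  req <- p$R_max * pl$concentration_M / (pl$concentration_M + p$K_D)
  expect_lt(max(abs(pl$R_eq - req) / req), 1e-3)
  expect_true(all(pl$equilibrated))
  expect_error(extract_plateau(simulate_1to1_sensorgram(p, d), window_s = 1e4),
               "longer than step")
})

test_that("plateau of a constant trace is that constant; short steps flagged", {
  tgrid <- seq(0, 20, 0.5)
  flat <- data.frame(sensor_id = "F", step = "assoc1", time_s = tgrid,
                     response_nm = 0.4, analyte = "x",
                     concentration_M = 1e-7, role = "sample")
  pl <- bli_plate(flat)
  out <- extract_plateau(pl, window_s = 5)
  expect_equal(out$R_eq, 0.4)
  # association cut off early (k_obs * t < 3): flagged unequilibrated
  p <- kinetic_params(1e5, 1e-3, 1)
  short <- assay_design(62.5e-9, t_assoc = 100, t_dissoc = 10, sample_rate = 5)
  out2 <- extract_plateau(simulate_1to1_sensorgram(p, short), window_s = 5)
  expect_false(out2$equilibrated[1])
})

test_that("steady-state fit recovers exact isotherm data", {
  # WT apoE4-like truth over the 0.012-50 uM two-fold series
  conc <- 50e-6 / 2^(12:0)
  kd_true <- 281e-9
  resp <- 1 * conc / (conc + kd_true)
  fit <- fit_steady_state(resp, conc)
  expect_true(fit$converged)
  expect_lt(abs(fit$K_D - kd_true) / kd_true, 1e-3)
  expect_lt(abs(fit$R_max - 1), 1e-3)
  expect_equal(fit$class, "binding")
})

test_that("steady-state fit agrees with the brute-force oracle", {
  set.seed(8)
  for (i in 1:5) {
    kd_true <- 10^runif(1, -7.5, -6)
    conc <- 2e-6 / 2^(5:0)
    resp <- 0.8 * conc / (conc + kd_true) + rnorm(6, 0, 0.004)
    fit <- fit_steady_state(resp, conc)
    orc <- oracle_isotherm_fit(conc, resp)
    expect_lt(abs(fit$K_D - orc$K_D) / orc$K_D, 1e-3)
    expect_lte(sum((resp - fit$fitted)^2), orc$sse * (1 + 1e-6))
  }
})

test_that("degenerate steady-state inputs are classified, not crashed", {
  conc <- nM_series()
  expect_equal(fit_steady_state(rep(0, 5), conc)$class, "no_binding_detected")
  # saturated design: all responses at R_max, K_D unidentifiable
  sat <- fit_steady_state(rep(1, 5) + c(0, 1e-9, 0, -1e-9, 0), conc)
  expect_true(any(grepl("ill_conditioned", sat$flags)))
  expect_error(fit_steady_state(c(1, 2), c(1e-9, 2e-9)), ">= 4")
})

test_that("noiseless parameter recovery holds across a K_D grid", {
  for (kd in c(1e-9, 5e-8, 1e-6, 1e-5)) {
    conc <- (kd * 16) / 2^(5:0)   # series spanning the truth
    resp <- 1.2 * conc / (conc + kd)
    fit <- fit_steady_state(resp, conc)
    expect_lt(abs(fit$K_D - kd) / kd, 1e-3)
  }
})

test_that("global kinetic fit recovers rates and flags model mismatch", {
  p <- kinetic_params(1e5, 1.65e-3, 1)  # K_D = 16.5 nM
  d <- assay_design(nM_series(), t_assoc = 600, t_dissoc = 600,
                    sample_rate = 1)
  pl <- double_reference(simulate_1to1_sensorgram(p, d))
  fit <- fit_kinetic_global(pl)
  expect_lt(abs(fit$k_on - p$k_on) / p$k_on, 1e-3)
  expect_lt(abs(fit$k_off - p$k_off) / p$k_off, 1e-3)
  expect_equal(fit$K_D, fit$k_off / fit$k_on)
  expect_length(fit$flags, 0)

  # zero analyte everywhere -> no binding
  zero <- pl
  zero$data$response_nm <- 0
  expect_equal(fit_kinetic_global(bli_plate(zero$data))$class,
               "no_binding_detected")

  # biphasic plate -> model mismatch flag
  bi <- simulate_biphasic_sensorgram(kinetic_params(1e5, 0.1, 1),
                                     kinetic_params(1e5, 1e-4, 1),
                                     c(0.5, 0.5), d)
  expect_true("model_mismatch" %in% fit_kinetic_global(double_reference(bi))$flags)
})

test_that("fold changes reproduce tabulated arithmetic with half-up rounding", {
  fc <- fold_change(55060, 281)
  expect_equal(fc$ratio_2dp, 195.94)
  expect_equal(fc$direction, "decrease")
  fc2 <- fold_change(25, 281)
  expect_equal(fc2$ratio_2dp, 11.24)
  expect_equal(fc2$direction, "increase")
  fc3 <- fold_change(281, 281)
  expect_equal(fc3$ratio_2dp, 1)
  expect_equal(fc3$direction, "none")
  expect_error(fold_change(-1, 2), "positive")

  # half-up differs from banker's rounding where it matters
  expect_equal(round_half_up(2.005, 2), 2.01)
  expect_equal(round_half_up(9.125, 2), 9.13)

  # symmetry: swapping arguments preserves ratio, flips direction
  set.seed(21)
  for (i in 1:20) {
    a <- 10^runif(1, 0, 5); b <- 10^runif(1, 0, 5)
    f1 <- fold_change(a, b); f2 <- fold_change(b, a)
    expect_equal(f1$ratio, f2$ratio)
    if (f1$direction != "none")
      expect_true(f1$direction != f2$direction)
  }
})

test_that("binding classification applies the response and fraction thresholds", {
  p <- kinetic_params(1e5, 1e-2, 1)
  d <- assay_design(nM_series(), t_assoc = 400, t_dissoc = 30, sample_rate = 2)
  wt <- simulate_1to1_sensorgram(p, d)
  expect_equal(classify_binding(wt, wt), "binding")
  # flat plate: nothing above threshold
  zero <- wt
  zero$data$response_nm <- 0
  expect_equal(classify_binding(bli_plate(zero$data)), "no_binding_detected")
  # 30% of WT plateau with a clear signal -> decreased at theta_frac 0.5
  weak <- wt
  weak$data$response_nm <- 0.3 * weak$data$response_nm
  expect_equal(classify_binding(bli_plate(weak$data), wt), "decreased_binding")
})

test_that("fit rows tabulate results with fold-change columns", {
  conc <- nM_series()
  fit <- fit_steady_state(0.9 * conc / (conc + 100e-9), conc)
  row <- fit_row("R76D", "IL-34", fit, wt_K_D = 16.5e-9)
  expect_equal(row$method, "steady_state")
  expect_equal(row$direction, "decrease")
  expect_equal(row$fold_vs_wt, round_half_up(fit$K_D / 16.5e-9, 2))
})
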