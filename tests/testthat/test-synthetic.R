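test_that("noiseless 1:1 traces follow the closed form everywhere", {
  p <- kinetic_params(1e5, 1e-2, 1)   # K_D = 100 nM
  d <- assay_design(c(50e-9, 100e-9, 400e-9), t_assoc = 40, t_dissoc = 30,
                    t_baseline = 2, sample_rate = 50)
  pl <- simulate_1to1_sensorgram(p, d)
  for (i in 1:3) {
    sg <- sensorgram(pl, sprintf("S%02d", i))
    conc <- sg$concentration_M[1]
    a <- sg[sg$step == "assoc1", ]
    ta <- a$time_s - a$time_s[1]
    kobs <- p$k_on * conc + p$k_off
    req <- p$R_max * conc / (conc + p$K_D)
    expect_lt(max(abs(a$response_nm - req * (1 - exp(-kobs * ta)))), 1e-10)
    ds <- sg[sg$step == "dissoc", ]
    td <- ds$time_s - ds$time_s[1]
    r_end <- a$response_nm[nrow(a)]
    expect_lt(max(abs(ds$response_nm - r_end * exp(-p$k_off * td))), 1e-10)
  }
  # worked point: C = K_D = 100 nM, t = 34.66 s -> R = 0.25 nm
  sg <- sensorgram(pl, "S02")
  a <- sg[sg$step == "assoc1", ]
  i <- which.min(abs(a$time_s - a$time_s[1] - 34.66))
  expect_equal(a$response_nm[i], 0.5 * (1 - exp(-0.02 * 34.66)),
               tolerance = 1e-12)
  expect_equal(a$response_nm[i], 0.25, tolerance = 1e-3)
  # initial condition: association starts at 0
  expect_equal(a$response_nm[1], 0)
  # half-saturation plateau at C = K_D after a long association
  dl <- assay_design(100e-9, t_assoc = 700, t_dissoc = 10, sample_rate = 2)
  sl <- sensorgram(simulate_1to1_sensorgram(p, dl), "S01")
  expect_equal(max(sl$response_nm[sl$step == "assoc1"]), 0.5,
               tolerance = 2e-4)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- kinetic_params(1e5, 1e-2, 1)
  d <- assay_design(c(1e-7, 2e-7), t_assoc = 20, t_dissoc = 10,
                    sample_rate = 5, noise_sd = 0.01, drift_rate = 1e-4,
                    seed = 99L)
  a <- simulate_1to1_sensorgram(p, d)
  b <- simulate_1to1_sensorgram(p, d)
  expect_identical(a$data, b$data)
  d2 <- assay_design(c(1e-7, 2e-7), t_assoc = 20, t_dissoc = 10,
                     sample_rate = 5, noise_sd = 0.01, drift_rate = 1e-4,
                     seed = 100L)
  expect_false(identical(simulate_1to1_sensorgram(p, d2)$data, a$data))
  # seeding is local: the global RNG stream is untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_1to1_sensorgram(p, d))
  expect_identical(.Random.seed, before)
})

test_that("invalid designs are rejected", {
  expect_error(assay_design(c(0, 1e-7), 10, 10), "positive")
  expect_error(assay_design(c(1e-7, 1e-7), 10, 10), "unique")
  expect_error(assay_design(1e-7, -1, 10), "positive")
  expect_error(assay_design(1e-7, 10, 10, noise_sd = -1), "noise_sd")
  expect_error(kinetic_params(-1, 1), "k_on")
  expect_error(kinetic_params(1e5, -1), "k_off")
})

test_that("biphasic mixtures degenerate correctly and are non-1:1", {
  pa <- kinetic_params(1e5, 0.1, 1)
  pb <- kinetic_params(1e5, 1e-4, 1)
  d <- assay_design(c(1e-7, 5e-7), t_assoc = 100, t_dissoc = 200,
                    sample_rate = 2)
  expect_error(simulate_biphasic_sensorgram(pa, pb, c(0.6, 0.6), d),
               "summing to 1")
  # (1, 0) mixture is the pure first component
  m <- simulate_biphasic_sensorgram(pa, pb, c(1, 0), d)
  s <- simulate_1to1_sensorgram(pa, d)
  expect_equal(m$data$response_nm, s$data$response_nm, tolerance = 1e-12)
  # identical components collapse to a single 1:1 trace
  m2 <- simulate_biphasic_sensorgram(pa, pa, c(0.5, 0.5), d)
  expect_equal(m2$data$response_nm, s$data$response_nm, tolerance = 1e-12)
  # half fast / half slow dissociation is visibly non-single-exponential
  mix <- simulate_biphasic_sensorgram(pa, pb, c(0.5, 0.5), d)
  sg <- sensorgram(mix, "S02")
  ds <- sg[sg$step == "dissoc", ]
  td <- ds$time_s - ds$time_s[1]
  expect_gt(oracle_single_exp_rel_resid(td, ds$response_nm), 0.02)
  # while the pure 1:1 dissociation is single-exponential
  sg1 <- sensorgram(s, "S02")
  d1 <- sg1[sg1$step == "dissoc", ]
  expect_lt(oracle_single_exp_rel_resid(d1$time_s - d1$time_s[1],
                                        d1$response_nm), 1e-5)
})

test_that("sequential simulator honours its limits and conserves occupancy", {
  p1 <- kinetic_params(1e5, 0, 1)
  p2 <- kinetic_params(1e5, 1e-3, 1)
  expect_error(sequential_design(p1, p2, 1e-6, 5e-7, overlap = 1.5),
               "overlap")
  # full blockade: saturating non-dissociating ligand 1, phi = 1
  pair <- competition_pair(1)
  expect_lt(abs(association2_gain(pair$competed)), 1e-3)
  # independence: phi = 0 reproduces the alone-arm gain
  pair0 <- competition_pair(0)
  expect_equal(association2_gain(pair0$competed),
               association2_gain(pair0$alone), tolerance = 1e-6)
  # intermediate overlap lies strictly between the limits
  g <- vapply(c(0, 0.5, 1), function(phi)
    association2_gain(competition_pair(phi)$competed), numeric(1))
  expect_true(g[2] < g[1] && g[2] > g[3])
  # occupancies stay physical; total occupancy bounded at phi = 1
  occ <- pair$competed$metadata$occupancy
  expect_true(all(occ$theta1 >= -1e-9 & occ$theta1 <= 1 + 1e-9))
  expect_true(all(occ$theta2 >= -1e-9 & occ$theta2 <= 1 + 1e-9))
  expect_true(all(occ$theta1 + occ$theta2 <= 1 + 1e-8))
})

test_that("planted motifs are complementary, detectable, and reproducible", {
  spec <- planted_motif_spec(8, 120, 30, seed = 5)
  f <- plant_complementary_motif(spec)
  expect_identical(plant_complementary_motif(spec), f)
  kd <- kyte_doolittle()
  ms <- sign(kd[strsplit(f$motif, "")[[1]]])
  ws <- sign(kd[strsplit(substr(f$target, 30, 37), "")[[1]]])
  expect_true(all(ms * ws < 0))
  expect_error(planted_motif_spec(10, 12, 5), "does not fit")
})
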