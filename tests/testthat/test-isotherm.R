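test_that("dilution trajectory matches hand evaluation of the perfusion formulas", {
  cfg <- zn_titration_config()
  traj <- dilution_trajectory(cfg)
  expect_equal(nrow(traj), 35L)
  expect_equal(traj$cum_volume[35], 274e-6)
  # hand evaluation at the final injection
  dV <- 274e-6; v <- 1.4e-3; r <- dV / (2 * v)
  expect_equal(traj$m_total[35], 50e-6 * (1 - r) / (1 + r), tolerance = 1e-14)
  expect_equal(traj$x_total[35], 1.5e-3 * (dV / v) / (1 + r), tolerance = 1e-14)
  expect_true(all(diff(traj$molar_ratio) > 0))
  expect_gt(max(traj$molar_ratio), 5)  # titration extends past 5 mol eq
  # empty schedule is legal and returns no rows
  empty <- titration_config(m_cell_0 = 5e-5, x_syringe = 1e-3,
                            schedule = injection_schedule(numeric()))
  expect_equal(nrow(dilution_trajectory(empty)), 0L)
})

test_that("overfilling the cell errors and half-filling warns", {
  big <- injection_schedule(rep(100e-6, 15))
  expect_error(titration_config(m_cell_0 = 5e-5, x_syringe = 1e-3,
                                schedule = big), "exceeds the cell volume")
  warn <- injection_schedule(rep(100e-6, 8))
  expect_warning(titration_config(m_cell_0 = 5e-5, x_syringe = 1e-3,
                                  schedule = warn), "half the cell volume")
})

test_that("no binding gives pure dilution heat; tight binding gives stoichiometric heats", {
  cfg <- zn_titration_config(dilution_heat = -2e-7)
  weak <- binding_model(site_class(1, 1e-3, -18e3))
  iso <- simulate_isotherm(weak, cfg)
  expect_lt(max(abs(iso$heats - -2e-7)), 1e-9)
  # K = 1e9: every early aliquot binds completely
  tight <- binding_model(site_class(1, 1e9, -30e3))
  cfg <- zn_titration_config()
  iso <- simulate_isotherm(tight, cfg)
  early <- which(iso$molar_ratio < 0.5)
  mol_inj <- cfg$x_syringe * cfg$schedule$volumes[early]
  expect_lt(max(abs(iso$heats[early] - -30e3 * mol_inj) /
                abs(-30e3 * mol_inj)), 0.01)
})

test_that("zero occupancy removes the high-affinity class entirely", {
  cfg <- zn_titration_config()
  full <- hsa_zn_model()
  iso0 <- simulate_isotherm(full, cfg, occupancy = 0)
  only2 <- binding_model(site_class(2, 2.5e4, -8e3))
  iso2 <- simulate_isotherm(only2, cfg)
  expect_equal(iso0$heats, iso2$heats, tolerance = 1e-12)
})

test_that("injection heats telescope back to the cumulative heat content", {
  cfg <- zn_titration_config(dilution_heat = 3e-8)
  iso <- simulate_isotherm(hsa_zn_model(), cfg)
  Q <- iso$Q
  Qprev <- c(0, Q[-length(Q)])
  displaced <- (cfg$schedule$volumes / cfg$v_cell) * (Q + Qprev) / 2
  lhs <- sum(iso$heats - cfg$dilution_heat)
  rhs <- Q[length(Q)] - 0 + sum(displaced)
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-9)
})

test_that("scaling cell and injection volumes together preserves molar ratios", {
  cfg1 <- zn_titration_config()
  cfg2 <- zn_titration_config(
    v_cell = 2.8e-3,
    schedule = injection_schedule(cfg1$schedule$volumes * 2))
  expect_equal(dilution_trajectory(cfg1)$molar_ratio,
               dilution_trajectory(cfg2)$molar_ratio, tolerance = 1e-14)
})

test_that("synthetic panels are seeded, reproducible and unbiased", {
  p1 <- make_synthetic_panel(c(1, 0.5), seed = 99)
  p2 <- make_synthetic_panel(c(1, 0.5), seed = 99)
  expect_identical(p1[[1]]$heats, p2[[1]]$heats)
  expect_identical(p1[[2]]$heats, p2[[2]]$heats)
  # zero noise reduces to the deterministic simulator
  p0 <- make_synthetic_panel(1, noise_sd = 0, seed = 1)
  expect_equal(p0[[1]]$heats,
               simulate_isotherm(hsa_zn_model(), zn_titration_config())$heats)
  # the mean of many noisy replicates converges on the noiseless isotherm
  truth <- simulate_isotherm(hsa_zn_model(), zn_titration_config())$heats
  sd0 <- 0.01 * max(abs(truth))
  set.seed(5)
  reps <- replicate(1000, truth + rnorm(length(truth), 0, sd0))
  dev <- abs(rowMeans(reps) - truth)
  expect_true(all(dev < 4.5 * sd0 / sqrt(1000)))
})

test_that("the palmitate panel encodes the two-arm study design", {
  panel <- palmitate_panel(seed = 1)
  expect_length(panel, 12L)
  arms <- vapply(panel, function(p) p$meta$arm, character(1))
  expect_equal(unname(table(arms)[c("WT", "FA2-KO")]), c(6L, 6L),
               ignore_attr = TRUE)
  th <- vapply(panel, function(p) p$meta$theta_true, numeric(1))
  expect_true(all(diff(th[arms == "WT"]) < 0))
  expect_true(all(th[arms == "FA2-KO"] == 1))
})
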