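truth <- c(N1 = 1, K1 = 2.9e5, H1 = -18e3, N2 = 2, K2 = 2.5e4, H2 = -8e3)

test_that("a noiseless isotherm is recovered exactly from a perturbed start", {
  iso <- simulate_isotherm(hsa_zn_model(), zn_titration_config())
  start <- binding_model(site_class(1.4, 9e5, -26e3),
                         site_class(1.6, 7e4, -4e3))
  fit <- fit_single_isotherm(iso, start, n_starts = 3, seed = 2)
  expect_true(fit$converged)
  expect_rel_equal(canonical_class_params(fit$params$value, 2),
                   unname(truth), 1e-6)
})

test_that("fixed parameters never move and all-fixed specs are rejected", {
  iso <- make_synthetic_panel(1, seed = 21)[[1]]
  specs <- fit_specs(hsa_zn_model(), fix = c("K1", "H1"))
  fit <- fit_single_isotherm(iso, hsa_zn_model(), specs = specs)
  expect_identical(fit$params$value[fit$params$name == "K1"], 2.9e5)
  expect_identical(fit$params$value[fit$params$name == "H1"], -18e3)
  expect_true(all(is.na(fit$params$se[fit$params$fixed])))
  all_fixed <- specs
  all_fixed$fixed <- TRUE
  expect_error(fit_single_isotherm(iso, hsa_zn_model(), specs = all_fixed),
               "all parameters are fixed")
})

test_that("fixing a parameter at its free optimum leaves chi2 unchanged", {
  iso <- make_synthetic_panel(1, seed = 31)[[1]]
  free_fit <- fit_single_isotherm(iso, hsa_zn_model())
  k1_hat <- free_fit$params$value[free_fit$params$name == "K1"]
  specs <- fit_specs(hsa_zn_model(), fix = "K1")
  specs$value[specs$name == "K1"] <- k1_hat
  refit <- fit_single_isotherm(iso, hsa_zn_model(), specs = specs)
  expect_lt(abs(refit$chi2 - free_fit$chi2) / free_fit$chi2, 1e-6)
})

test_that("fitting in K and in log10(K) reach the same optimum", {
  iso <- make_synthetic_panel(1, seed = 41)[[1]]
  f_log <- fit_single_isotherm(iso, hsa_zn_model(), log_k = TRUE)
  f_lin <- fit_single_isotherm(iso, hsa_zn_model(), log_k = FALSE)
  expect_rel_equal(f_log$params$value, f_lin$params$value, 1e-4)
})

test_that("near-degenerate site classes raise the identifiability flag", {
  m_close <- binding_model(site_class(1, 1e5, -15e3),
                           site_class(1, 5e4, -10e3))
  iso <- make_synthetic_panel(1, model = m_close, seed = 3)[[1]]
  fit <- fit_single_isotherm(iso, m_close)
  expect_true(fit$high_correlation)
  expect_gt(max(abs(fit$cor[upper.tri(fit$cor)])), 0.95)
})

test_that("a knocked-out high-affinity site fits to zero stoichiometry", {
  # generator lacks the high-affinity class; fit with K1/H1 fixed at the
  # wild-type values and stoichiometries free
  ko <- binding_model(site_class(2, 2.5e4, -8e3))
  iso_ko <- make_synthetic_panel(1, model = ko, seed = 51)[[1]]
  specs <- fit_specs(hsa_zn_model(), fix = c("K1", "H1"))
  fit <- fit_single_isotherm(iso_ko, hsa_zn_model(), specs = specs,
                             n_starts = 8, seed = 1)
  expect_lt(fit$params$value[fit$params$name == "N1"], 0.05)
  expect_equal(fit$params$value[fit$params$name == "N2"], 2, tolerance = 0.1)
})

test_that("attenuated stoichiometries are recovered with all K and dH fixed", {
  atten <- binding_model(site_class(0.5, 2.9e5, -18e3),
                         site_class(0.35, 2.5e4, -8e3))
  iso <- make_synthetic_panel(1, model = atten, seed = 61,
                              noise_sd = 1e-7)[[1]]
  specs <- fit_specs(hsa_zn_model(), fix = c("K1", "H1", "K2", "H2"))
  fit <- fit_single_isotherm(iso, hsa_zn_model(), specs = specs)
  expect_equal(fit$params$value[fit$params$name == "N1"], 0.5,
               tolerance = 0.05)
  expect_equal(fit$params$value[fit$params$name == "N2"], 0.35,
               tolerance = 0.05)
})

test_that("three-class fatty-acid fits recover constants with fixed stoichiometries", {
  cfg <- myristate_titration_config()
  iso <- make_synthetic_panel(1, model = hsa_myristate_model(), config = cfg,
                              seed = 71)[[1]]
  specs <- fit_specs(hsa_myristate_model(), fix = c("N1", "N2", "N3"))
  fit <- fit_single_isotherm(iso, hsa_myristate_model(), specs = specs)
  expect_true(fit$converged)
  k_hat <- fit$params$value[fit$params$name %in% c("K1", "K2", "K3")]
  k_true <- c(1.76e6, 3.91e5, 3.11e4)
  se <- fit$params$se[fit$params$name %in% c("K1", "K2", "K3")]
  expect_true(all(abs(k_hat - k_true) < pmax(4 * se, 0.1 * k_true)))
})
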