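test_that("trivial equilibria are exact", {
  m <- binding_model(site_class(1, 1e6, -20e3))
  st <- solve_free_ligand(m, m_total = 5e-5, x_total = 0)
  expect_identical(st$x_free, 0)
  expect_identical(st$theta, 0)
  st <- solve_free_ligand(m, m_total = 0, x_total = 1e-4)
  expect_identical(st$x_free, 1e-4)
})

test_that("single-class solver matches the closed-form quadratic root", {
  K <- 1e6
  m <- binding_model(site_class(1, K, -20e3))
  st <- solve_free_ligand(m, m_total = 5e-5, x_total = 2.5e-5)
  expect_rel_equal(st$x_free, quad_free_ligand(K, 5e-5, 2.5e-5), 1e-10)
  expect_equal(st$theta, K * st$x_free / (1 + K * st$x_free))
})

test_that("multi-class solver agrees with a pure-bisection oracle", {
  set.seed(11)
  n_draw <- 200L
  nmat <- matrix(runif(2 * n_draw, 0.5, 4), n_draw, 2)
  Kmat <- matrix(10^runif(2 * n_draw, 3, 8), n_draw, 2)
  mt <- 10^runif(n_draw, -6, -4)
  xt <- 10^runif(n_draw, -6, -3)
  oracle <- bisect_free_ligand(nmat, Kmat, mt, xt)
  got <- vapply(seq_len(n_draw), function(i) {
    mod <- binding_model(site_class(nmat[i, 1], Kmat[i, 1], -1e4),
                         site_class(nmat[i, 2], Kmat[i, 2], -1e4))
    solve_free_ligand(mod, mt[i], xt[i])$x_free
  }, numeric(1))
  expect_lt(max(abs(got - oracle) / xt), 1e-11)
})

test_that("mass balance is conserved over random draws", {
  set.seed(7)
  for (i in 1:300) {
    nc <- sample(1:3, 1)
    mod <- binding_model(lapply(seq_len(nc), function(j)
      site_class(runif(1, 0, 4), 10^runif(1, 2, 9), rnorm(1, 0, 2e4))))
    mt <- 10^runif(1, -6, -4)
    xt <- 10^runif(1, -7, -3)
    st <- solve_free_ligand(mod, mt, xt)
    mats <- alloitc:::.model_mats(mod)
    bound <- mt * sum(mats$n * st$theta)
    expect_lt(abs(st$x_free + bound - xt), 1e-10 * xt)
    expect_true(all(st$theta >= 0 & st$theta <= 1))
    expect_true(st$x_free >= 0 && st$x_free <= xt)
  }
})

test_that("free ligand increases strictly with total ligand", {
  mod <- binding_model(site_class(1, 2.9e5, -18e3), site_class(2, 2.5e4, -8e3))
  xt <- seq(1e-6, 5e-4, length.out = 60)
  xf <- vapply(xt, function(x) solve_free_ligand(mod, 5e-5, x)$x_free,
               numeric(1))
  expect_true(all(diff(xf) > 0))
})

test_that("class order and splitting do not change the physics", {
  a <- site_class(1, 2.9e5, -18e3)
  b <- site_class(2, 2.5e4, -8e3)
  m1 <- binding_model(a, b)
  m2 <- binding_model(b, a)  # canonicalised to the same order
  s1 <- solve_free_ligand(m1, 5e-5, 1e-4)
  s2 <- solve_free_ligand(m2, 5e-5, 1e-4)
  expect_identical(s1$x_free, s2$x_free)
  expect_identical(heat_content(s1, m1, 1.4e-3), heat_content(s2, m2, 1.4e-3))
  # one class of n = 2 behaves exactly like two identical classes of n = 1
  m_two <- binding_model(site_class(2, 2.5e4, -8e3))
  m_split <- binding_model(site_class(1, 2.5e4, -8e3),
                           site_class(1, 2.5e4, -8e3))
  s_two <- solve_free_ligand(m_two, 5e-5, 1e-4)
  s_split <- solve_free_ligand(m_split, 5e-5, 1e-4)
  expect_equal(s_two$x_free, s_split$x_free, tolerance = 1e-12)
  expect_equal(heat_content(s_two, m_two, 1.4e-3),
               heat_content(s_split, m_split, 1.4e-3), tolerance = 1e-12)
  # a zero-stoichiometry class is removable without effect
  m_zero <- binding_model(site_class(0, 1e9, -5e4), a, b)
  expect_equal(solve_free_ligand(m_zero, 5e-5, 1e-4)$x_free, s1$x_free,
               tolerance = 1e-12)
})

test_that("heat content follows the saturation limit and the analytic root", {
  mod <- binding_model(site_class(1, 1e6, 0), site_class(2, 1e4, 0))
  st <- solve_free_ligand(mod, 5e-5, 1e-4)
  expect_identical(heat_content(st, mod, 1.4e-3), 0)
  mod <- binding_model(site_class(1, 1e6, -20e3), site_class(2, 1e4, -5e3))
  cap <- binding_capacity(mod)
  st <- solve_free_ligand(mod, 5e-5, 1e4 * cap * 5e-5)
  q_sat <- 1.4e-3 * 5e-5 * (1 * -20e3 + 2 * -5e3)
  expect_lt(abs(heat_content(st, mod, 1.4e-3) - q_sat) / abs(q_sat), 1e-3)
  # composition with the quadratic oracle
  K <- 1e6
  mod1 <- binding_model(site_class(1, K, -20e3))
  st1 <- solve_free_ligand(mod1, 5e-5, 2.5e-5)
  xf <- quad_free_ligand(K, 5e-5, 2.5e-5)
  th <- K * xf / (1 + K * xf)
  expect_rel_equal(heat_content(st1, mod1, 1.4e-3),
                   1.4e-3 * 5e-5 * 1 * -20e3 * th, 1e-10)
})

test_that("mismatched state and model are rejected", {
  m1 <- binding_model(site_class(1, 1e6, -20e3))
  m2 <- binding_model(site_class(1, 1e6, -20e3), site_class(1, 1e4, -5e3))
  st <- solve_free_ligand(m1, 5e-5, 2.5e-5)
  expect_error(heat_content(st, m2, 1.4e-3), "site classes")
})
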