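test_that("complete-data sandwich equals the classical robust sandwich of
           profile least squares", {
  toy <- make_complete_toy(n = 250, seed = 8, hetero = TRUE)
  fit <- gplm_fit(toy$data, "naive", h = 0.2)
  oracle <- oracle_profile_ls(toy$data$y, toy$data$x, toy$data$z, 0.2)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-8)
  expect_equal(unname(fit$omega), unname(oracle$omega), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-6)
})

test_that("nuisance-model corrections are zero when pi is known and delta
           fixed", {
  cfg <- sim_config(n = 400, seed = 10)
  sim <- simulate_gplm_data(cfg, rep = 1)
  fit <- gplm_fit(sim$data, "aipw", h = 0.15, pi_known = sim$pi,
                  delta_fixed = sim$delta)
  sw <- sandwich_beta(sim$data, fit$nuis, fit$beta, fit$theta, "aipw")
  # with no estimated nuisances the meat is exactly the outer product of
  # the raw influence terms D_i eps_i
  raw <- crossprod(sw$psi) / sim$data$n
  expect_equal(sw$meat, raw, tolerance = 1e-12)
  expect_true(all(eigen(sw$omega, only.values = TRUE)$values >= -1e-10))
})

test_that("sandwich and pointwise variance are permutation invariant", {
  cfg <- sim_config(n = 300, seed = 18)
  sim <- simulate_gplm_data(cfg, rep = 1)
  d <- sim$data
  fit <- gplm_fit(d, "aipw", h = 0.2, pi_known = sim$pi,
                  delta_fixed = sim$delta, z_grid = seq(0.2, 0.8, 0.1))
  set.seed(1)
  perm <- sample(d$n)
  d2 <- observed_data(d$y[perm], d$x[perm, , drop = FALSE], d$z[perm],
                      d$u[perm, , drop = FALSE], r = d$r[perm])
  fit2 <- gplm_fit(d2, "aipw", h = 0.2, pi_known = sim$pi[perm],
                   delta_fixed = sim$delta[perm],
                   z_grid = seq(0.2, 0.8, 0.1))
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-9)
  expect_equal(fit$omega, fit2$omega, tolerance = 1e-8)
  expect_equal(fit$theta_var_grid, fit2$theta_var_grid, tolerance = 1e-8)
})

test_that("pointwise variance reduces to the textbook local-linear form
           in the homoskedastic complete-data case", {
  toy <- make_complete_toy(n = 400, seed = 22, sd = 0.7)
  d <- toy$data
  fit <- gplm_fit(d, "naive", h = 0.2, z_grid = seq(0.3, 0.7, 0.1))
  # independent evaluation of c0 * avg_loc(eps^2) / (n h f-hat t-hat^2)
  # with t-hat = avg_loc(1), written from scratch
  mu <- d$x[, 1] * fit$beta + fit$theta$alpha0[match(d$z,
                                                    fit$theta$z_eval)]
  eps2 <- (d$y - mu)^2
  n <- d$n; h <- 0.2
  h_f <- 0.9 * min(stats::sd(d$z), stats::IQR(d$z) / 1.34) * n^(-1 / 5)
  v_orc <- vapply(seq(0.3, 0.7, 0.1), function(z0) {
    kk <- 0.75 * pmax(1 - ((d$z - z0) / h)^2, 0) / h
    fz <- mean(0.75 * pmax(1 - ((d$z - z0) / h_f)^2, 0) / h_f)
    (3 / 5) * (sum(kk * eps2) / sum(kk)) / (fz * (n * h) * 1)
  }, numeric(1))
  expect_equal(fit$theta_var_grid, v_orc, tolerance = 1e-6)
})

test_that("pi == 1 collapses the AIPW, IPW and naive variance formulas", {
  toy <- make_complete_toy(n = 200, seed = 24)
  d <- toy$data
  nuis <- gplm_nuisance(pi = 1, delta = rnorm(200), v = 1, n = 200)
  zg <- seq(0.3, 0.7, 0.2)
  th <- theta_curve(d, nuis, toy$beta, sort(unique(c(d$z, zg))), 0.2,
                    "aipw")
  va <- theta_pointwise_variance(d, nuis, toy$beta, th, zg, "aipw",
                                 h = 0.2)
  vi <- theta_pointwise_variance(d, nuis, toy$beta, th, zg, "ipw",
                                 h = 0.2)
  vn <- theta_pointwise_variance(d, nuis, toy$beta, th, zg, "naive",
                                 h = 0.2)
  expect_equal(va, vi, tolerance = 1e-12)
  expect_equal(va, vn, tolerance = 1e-12)
})

test_that("plug-in variance of the optimal AIPW curve is no larger than
           the IPW curve's at every interior point", {
  cfg <- sim_config(n = 2000, seed = 33)
  sim <- simulate_gplm_data(cfg, rep = 1)
  d <- sim$data
  zg <- seq(0.1, 0.9, by = 0.05)
  za <- sort(unique(c(d$z, zg)))
  nu_a <- gplm_nuisance(sim$pi, sim$delta, v = 1)
  nu_i <- gplm_nuisance(sim$pi, NULL, v = 1)
  th_a <- theta_curve(d, nu_a, 2, za, 0.15, "aipw")
  th_i <- theta_curve(d, nu_i, 2, za, 0.15, "ipw")
  va <- theta_pointwise_variance(d, nu_a, 2, th_a, zg, "aipw", h = 0.15)
  vi <- theta_pointwise_variance(d, nu_i, 2, th_i, zg, "ipw", h = 0.15)
  expect_true(all(va <= vi * 1.05))
})

test_that("efficiency bound matches its analytic closed form when nothing
           is missing", {
  # pi == 1 and homoskedastic eps*: bound = (sigma_y^2 + var(U|X,Z)) /
  # E[(X - E[X|Z])^2]
  cfg <- sim_config(tau0 = 30)
  b <- efficiency_bound_mc(cfg, n_outer = 2e4, n_inner = 200, seed = 5)
  analytic <- (cfg$sigma_y^2 + 3 + 2 * cfg$noise_sd_u^2) / 1
  expect_lt(abs(b$v_eff[1, 1] - analytic), 3 * b$mc_se[1, 1] + 0.02)
})

test_that("efficiency bound is stable across Monte Carlo seeds", {
  vals <- vapply(1:3, function(s)
    efficiency_bound_mc(sim_config(), n_outer = 5000, n_inner = 150,
                        seed = s)$v_eff[1, 1], numeric(1))
  ses <- vapply(1:3, function(s)
    efficiency_bound_mc(sim_config(), n_outer = 5000, n_inner = 150,
                        seed = s)$mc_se[1, 1], numeric(1))
  expect_lt(max(vals) - min(vals), 3 * max(ses) * 2)
})
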