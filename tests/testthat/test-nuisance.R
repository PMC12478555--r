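test_that("missingness MLE matches cell proportions on a saturated design", {
  u <- c(1, 1, 1, 1, 0, 0, 0, 0)
  r <- c(1, 1, 1, 0, 1, 0, 0, 0)   # 3/4 in cell u=1, 1/4 in cell u=0
  d <- observed_data(y = ifelse(r == 1, rnorm(8), NA), x = rnorm(8),
                     z = (1:8) / 8, u = u, r = r)
  fit <- fit_missingness(d, design = cbind(1, u), pi_floor = 0)
  expect_equal(unname(fit$pi[u == 1]), rep(0.75, 4), tolerance = 1e-6)
  expect_equal(unname(fit$pi[u == 0]), rep(0.25, 4), tolerance = 1e-6)
  # score has mean ~ 0 at the MLE
  expect_lt(max(abs(colMeans(fit$score))), 1e-8)
})

test_that("degenerate and singular missingness designs are detected", {
  d <- observed_data(y = rnorm(8), x = rnorm(8), z = (1:8) / 8)
  expect_error(fit_missingness(d, design = matrix(1, 8, 1)),
               "non-overlap")
  r <- c(1, 0, 1, 0, 1, 0, 1, 0)
  d2 <- observed_data(y = ifelse(r == 1, rnorm(8), NA), x = rnorm(8),
                      z = (1:8) / 8, r = r)
  w <- cbind(a = rep(1, 8), b = rep(2, 8))
  expect_error(fit_missingness(d2, design = w), "offending columns: b")
})

test_that("missingness MLE recovers the selection parameters at n = 5000", {
  cfg <- sim_config(n = 5000, seed = 13)
  sim <- simulate_gplm_data(cfg, rep = 1)
  w <- cbind(1, pmin(pmax(sim$data$u[, 1] - cfg$a1, 0), cfg$a2 - cfg$a1))
  fit <- fit_missingness(sim$data, design = w, pi_floor = 0)
  ses <- sqrt(diag(solve(-fit$dscore)) / cfg$n)
  expect_lt(abs(fit$tau[1] - cfg$tau0), 3 * ses[1])
  expect_lt(abs(fit$tau[2] - cfg$tau1), 3 * ses[2])
})

test_that("outcome model interpolates exact linear data and ignores
           constant weights", {
  set.seed(5)
  n <- 40
  x <- rnorm(n); u <- rnorm(n); z <- runif(n)
  y <- 1 + 2 * x + 3 * u
  r <- rbinom(n, 1, 0.7)
  d <- observed_data(ifelse(r == 1, y, NA), x, z, u, r = r)
  des <- cbind(1, x, u)
  fit <- fit_outcome_model(d, des)
  expect_equal(fit$delta, y, tolerance = 1e-10)
  fit_w <- fit_outcome_model(d, des, weights = rep(4, n))
  expect_equal(fit$eta, fit_w$eta, tolerance = 1e-10)
  expect_error(fit_outcome_model(d, cbind(des, x)), "rank-deficient")
})

test_that("complete-case least squares is consistent for E(Y|X,Z,U)", {
  cfg <- sim_config(n = 5000, seed = 21)
  sim <- simulate_gplm_data(cfg, rep = 1)
  des <- cbind(1, sim$data$x[, 1], sim$data$u[, 1], sim$m_z)
  fit <- fit_outcome_model(sim$data, des)
  # oracle large-n refit on the latent complete data
  oracle <- stats::lm.fit(des, sim$y_full)$coefficients
  se <- sqrt(diag(solve(crossprod(des[sim$data$r == 1, ]))) *
               stats::var(as.numeric(sim$y_full - des %*% oracle)))
  expect_true(all(abs(fit$eta - c(0, 1, 1, 1)) < 3 * se + 0.05))
})

test_that("working variance: constant family closed forms", {
  set.seed(6)
  n <- 60
  z <- runif(n); x <- rnorm(n)
  y <- x + z + rnorm(n)
  d <- observed_data(y, x, z)   # no missingness
  q <- x + z
  vf <- fit_working_variance(d, pi = rep(1, n), delta = rnorm(n), q = q)
  expect_equal(vf$zeta, mean((y - q)^2))      # pi terms collapse at R == 1
  r <- rbinom(n, 1, 0.6); r[1:3] <- 1
  d2 <- observed_data(ifelse(r == 1, y, NA), x, z, r = r)
  pi <- rep(0.6, n); delta <- q + 0.3
  s <- ((r / pi) * (ifelse(r == 1, y, 0) - q) -
          (r / pi - 1) * (delta - q))^2
  vf2 <- fit_working_variance(d2, pi, delta, q)
  expect_equal(vf2$zeta, mean(s))
  vf3 <- fit_working_variance(d2, pi, NULL, q, ipw = TRUE)
  expect_equal(vf3$zeta, mean((r / pi) * (ifelse(r == 1, y, 0) - q)^2))
})

test_that("working variance matches the Monte Carlo variance of the
           weighted residual at the truth", {
  cfg <- sim_config(n = 5000, seed = 31)
  sim <- simulate_gplm_data(cfg, rep = 1)
  q <- sim$data$x[, 1] * 2 + true_theta(sim$data$z, cfg)
  vf <- fit_working_variance(sim$data, sim$pi, sim$delta, q)
  # brute-force Monte Carlo of eps*_delta from its definition on a fresh
  # large draw
  big <- simulate_gplm_data(sim_config(n = 200000, seed = 77), rep = 1)
  qb <- big$data$x[, 1] * 2 + true_theta(big$data$z, cfg)
  y0 <- ifelse(is.na(big$data$y), 0, big$data$y)
  wr <- big$data$r / big$pi
  eps_star <- wr * (y0 - qb) - (wr - 1) * (big$delta - qb)
  mc <- mean(eps_star^2)
  mc_se <- stats::sd(eps_star^2) / sqrt(length(eps_star))
  fit_se <- stats::sd(vf$s) / sqrt(cfg$n)
  expect_lt(abs(vf$zeta - mc), 3 * (mc_se + fit_se))
})

test_that("log-linear variance family fits a positive variance function", {
  set.seed(9)
  n <- 400
  z <- runif(n); x <- rnorm(n)
  lp <- x + z
  y <- lp + rnorm(n, 0, exp(0.2 * lp))
  d <- observed_data(y, x, z)
  vf <- fit_working_variance(d, rep(1, n), NULL, lp, family = "loglinear",
                             ipw = TRUE, lp = lp)
  expect_true(all(vf$v_of(seq(-2, 2, by = 0.5)) > 0))
  expect_gt(vf$zeta[2], 0)   # variance increases with the linear predictor
})

test_that("initial estimator equals unweighted profile least squares when
           nothing is missing", {
  toy <- make_complete_toy(n = 150, seed = 3)
  init <- initial_fit(toy$data, pi = rep(1, 150), h = 0.2)
  oracle <- oracle_profile_ls(toy$data$y, toy$data$x, toy$data$z, 0.2)
  expect_equal(init$beta_check, oracle$beta, tolerance = 1e-10)
})

test_that("initial estimator is root-n consistent on the two-stage design", {
  cfg <- sim_config(n = 500, seed = 17)
  hits <- 0L
  reps <- 60
  for (k in seq_len(reps)) {
    sim <- simulate_gplm_data(cfg, rep = k)
    init <- initial_fit(sim$data, pi = sim$pi, h = 0.15)
    if (abs(init$beta_check - 2) < 0.5) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})
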