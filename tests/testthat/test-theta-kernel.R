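test_that("identity-link local solve equals closed-form weighted least
           squares", {
  cfg <- sim_config(n = 300, seed = 2)
  sim <- simulate_gplm_data(cfg, rep = 1)
  d <- sim$data
  nuis <- gplm_nuisance(sim$pi, sim$delta, v = 1.3)
  beta <- 1.8
  for (z0 in c(0.3, 0.55, 0.8)) {
    sol <- solve_local(d, nuis, beta, z0, h = 0.2, estimator = "aipw")
    y0 <- ifelse(is.na(d$y), 0, d$y)
    wr <- d$r / nuis$pi
    ystar <- wr * y0 - (wr - 1) * nuis$delta
    kk <- kernel_weights(d$z, z0, 0.2)
    oracle <- oracle_local_linear(d$z, z0, 0.2, rep(1 / 1.3, d$n),
                                  ystar - d$x[, 1] * beta)
    expect_equal(sol$alpha, oracle, tolerance = 1e-10)
    expect_true(sol$converged)
  }
})

test_that("augmentation vanishes when delta equals the fitted mean:
           AIPW root = IPW root", {
  cfg <- sim_config(n = 400, seed = 5)
  sim <- simulate_gplm_data(cfg, rep = 1)
  d <- sim$data
  beta <- 2
  nuis_ipw <- gplm_nuisance(sim$pi, NULL, v = 1)
  z0 <- 0.5
  ipw <- solve_local(d, nuis_ipw, beta, z0, h = 0.25, estimator = "ipw")
  # set delta_i identically to the fitted mean at the IPW root
  mu_at_root <- d$x[, 1] * beta + ipw$alpha[1] + ipw$alpha[2] * (d$z - z0)
  nuis_a <- gplm_nuisance(sim$pi, mu_at_root, v = 1)
  aipw <- solve_local(d, nuis_a, beta, z0, h = 0.25, estimator = "aipw")
  expect_equal(aipw$alpha, ipw$alpha, tolerance = 1e-7)
})

test_that("logit-link local solve matches a derivative-free grid-search
           oracle", {
  set.seed(11)
  n <- 200
  z <- runif(n)
  x <- matrix(rnorm(n), n, 1)
  beta <- 0.8
  theta0 <- 0.5 - z
  pr <- plogis(x[, 1] * beta + theta0)
  y <- rbinom(n, 1, pr)
  r <- rbinom(n, 1, 0.8); r[1:5] <- 1
  d <- observed_data(ifelse(r == 1, y, NA), x, z, r = r)
  pi <- rep(0.8, n)
  delta <- pr                      # fixed augmentation values
  nuis <- gplm_nuisance(pi, delta, v = 1)
  z0 <- 0.5; h <- 0.4
  sol <- solve_local(d, nuis, beta, z0, h, estimator = "aipw",
                     link = "logit",
                     control = gplm_control(local_tol = 1e-12))
  # independent oracle: nested grid refinement of the estimating-equation
  # norm over (alpha0, alpha1)
  lk <- make_link("logit")
  y0 <- ifelse(is.na(d$y), 0, d$y)
  wr <- d$r / pi
  kk <- 0.75 * pmax(1 - ((z - z0) / h)^2, 0) / h
  ee_norm <- function(a0, a1) {
    eta <- x[, 1] * beta + a0 + a1 * (z - z0)
    mu <- lk$mu(eta)
    b <- wr * (y0 - mu) - (wr - 1) * (delta - mu)
    f1 <- sum(kk * lk$mu1(eta) * b)
    f2 <- sum(kk * lk$mu1(eta) * (z - z0) * b)
    sqrt(f1^2 + f2^2)
  }
  ctr <- c(0, 0); span <- c(3, 6)
  for (round in 1:9) {
    a0g <- seq(ctr[1] - span[1], ctr[1] + span[1], length.out = 41)
    a1g <- seq(ctr[2] - span[2], ctr[2] + span[2], length.out = 41)
    vals <- outer(a0g, a1g, Vectorize(ee_norm))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    ctr <- c(a0g[ij[1]], a1g[ij[2]])
    span <- span * 0.1
  }
  expect_lt(max(abs(sol$alpha - ctr)), 1e-6)
})

test_that("a constant curve is interpolated exactly without noise or
           missingness", {
  set.seed(3)
  n <- 120
  z <- runif(n)
  x <- matrix(rnorm(n), n, 1)
  y <- 2 * x[, 1] + 7
  d <- observed_data(y, x, z)
  nuis <- gplm_nuisance(pi = 1, v = 1, n = n)
  th <- theta_curve(d, nuis, beta = 2, z_eval = seq(0.2, 0.8, by = 0.1),
                    h = 0.25, estimator = "naive")
  expect_equal(th$alpha0, rep(7, 7), tolerance = 1e-10)
  expect_equal(th$alpha1, rep(0, 7), tolerance = 1e-8)
})

test_that("smoothing bias scales as h^2 (quartering when h halves)", {
  set.seed(12)
  n <- 8000
  z <- runif(n)
  x <- matrix(0, n, 1)
  theta <- function(z) sin(2 * pi * z) + 2
  y <- theta(z)                    # no noise: estimate = smoothed truth
  d <- observed_data(y, x, z)
  nuis <- gplm_nuisance(pi = 1, v = 1, n = n)
  z0 <- 0.25                       # curvature extreme of sin
  b <- vapply(c(0.05, 0.1), function(h) {
    theta_curve(d, nuis, 0, z0, h, "naive")$alpha0 - theta(z0)
  }, numeric(1))
  expect_gt(b[2] / b[1], 3)
  expect_lt(b[2] / b[1], 5)
})

test_that("curve recovery: AIPW sup-error shrinks with the sample size at
           the kernel rate", {
  zg <- seq(0.1, 0.9, by = 0.05)
  sup_err <- function(n, h, reps, seed) {
    cfg <- sim_config(n = n, seed = seed)
    vapply(seq_len(reps), function(k) {
      sim <- simulate_gplm_data(cfg, rep = k)
      nuis <- gplm_nuisance(sim$pi, sim$delta, v = 1)
      th <- theta_curve(sim$data, nuis, 2, zg, h, "aipw", phi = FALSE)
      max(abs(th$alpha0 - true_theta(zg, cfg)))
    }, numeric(1))
  }
  small <- sup_err(500, 0.15, 15, seed = 23)
  big <- sup_err(4000, 0.08, 15, seed = 23)
  # (nh)^(-1/2) + h^2 scaling predicts roughly a halving of the error
  expect_lt(stats::median(big), 0.7 * stats::median(small))
  expect_lt(stats::median(big), 0.5)
})

test_that("phi: closed form, implicit differentiation and finite
           differences agree", {
  cfg <- sim_config(n = 300, seed = 7)
  sim <- simulate_gplm_data(cfg, rep = 1)
  d <- sim$data
  nuis <- gplm_nuisance(sim$pi, sim$delta, v = 1)
  zg <- seq(0.2, 0.8, by = 0.1)
  th <- theta_curve(d, nuis, 2, zg, h = 0.2, "aipw")
  fd <- phi_derivative(d, nuis, 2, th, "aipw", method = "fd")
  expect_lt(max(abs(th$phi - fd)), 1e-6)
  # identity-link closed form: phi = -(local-linear smooth of X)
  for (i in seq_along(zg)) {
    sm <- oracle_local_linear(d$z, zg[i], 0.2, rep(1, d$n), d$x[, 1])
    expect_equal(th$phi[i, 1], -sm[1], tolerance = 1e-10)
  }
})

test_that("phi by implicit differentiation matches finite differences for
           the logit link", {
  set.seed(14)
  n <- 250
  z <- runif(n)
  x <- matrix(rnorm(n), n, 1)
  pr <- plogis(0.7 * x[, 1] + 0.5 - z)
  y <- rbinom(n, 1, pr)
  d <- observed_data(y, x, z)
  nuis <- gplm_nuisance(pi = 1, delta = pr, v = 1, n = n)
  zg <- c(0.35, 0.5, 0.65)
  ctl <- gplm_control(local_tol = 1e-12)
  th <- theta_curve(d, nuis, 0.7, zg, h = 0.35, "aipw", link = "logit",
                    control = ctl)
  an <- phi_derivative(d, nuis, 0.7, th, "aipw", link = "logit",
                       control = ctl, method = "analytic")
  fd <- phi_derivative(d, nuis, 0.7, th, "aipw", link = "logit",
                       control = ctl, method = "fd")
  expect_lt(max(abs(an - fd)), 1e-4)
})

test_that("with no missing outcomes the three estimators coincide", {
  toy <- make_complete_toy(n = 200, seed = 19)
  d <- toy$data
  nuis <- gplm_nuisance(pi = 1, delta = rnorm(200), v = 1, n = 200)
  zg <- seq(0.1, 0.9, by = 0.1)
  ths <- lapply(c("naive", "ipw", "aipw"), function(est)
    theta_curve(d, nuis, toy$beta, zg, h = 0.2, est, phi = FALSE))
  expect_equal(ths[[1]]$alpha0, ths[[2]]$alpha0, tolerance = 1e-12)
  expect_equal(ths[[1]]$alpha0, ths[[3]]$alpha0, tolerance = 1e-12)
})

test_that("narrow windows raise informative bandwidth errors", {
  d <- observed_data(y = rnorm(10), x = rnorm(10), z = (1:10) / 10)
  nuis <- gplm_nuisance(pi = 1, v = 1, n = 10)
  expect_error(solve_local(d, nuis, 0, z0 = 0.5, h = 0.01,
                           estimator = "naive"),
               "increase the bandwidth")
})
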