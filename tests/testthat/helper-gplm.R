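# Shared fixtures and independent oracles for the test suite.

# Complete-data partially linear toy: identity link, no missingness.
make_complete_toy <- function(n = 300, seed = 1, p = 1, sd = 0.5,
                              hetero = FALSE) {
  set.seed(seed)
  z <- runif(n)
  x <- matrix(rnorm(n * p, 0.5 * z, 1), n, p)
  theta <- sin(2 * pi * z) + 2
  beta <- seq_len(p)
  sdv <- if (hetero) sd * (0.5 + z) else rep(sd, n)
  y <- as.numeric(x %*% beta) + theta + rnorm(n, 0, sdv)
  list(data = observed_data(y = y, x = x, z = z),
       beta = beta, theta = theta)
}

# Independent local-linear WLS oracle: explicit (G'WG)^{-1} G'W y solve at
# one point, written without any package smoothing code.
oracle_local_linear <- function(z_obs, z0, h, w, resp) {
  kk <- 0.75 * pmax(1 - ((z_obs - z0) / h)^2, 0) / h
  ww <- kk * w
  G <- cbind(1, z_obs - z0)
  a <- solve(t(G) %*% (ww * G), t(G) %*% (ww * resp))
  as.numeric(a)
}

# Textbook profile least-squares oracle for identity link, complete data:
# dense smoother matrix, residualized covariates, classical robust
# sandwich. Independent of the package's chunked implementation.
oracle_profile_ls <- function(y, x, z, h) {
  n <- length(y)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    kk <- 0.75 * pmax(1 - ((z - z[i]) / h)^2, 0) / h
    G <- cbind(1, z - z[i])
    M <- solve(t(G) %*% (kk * G), t(G %*% diag(1, 2)) %*% diag(kk))
    L[i, ] <- M[1, ]
  }
  xs <- x - L %*% x
  ys <- y - as.numeric(L %*% y)
  beta <- solve(t(xs) %*% xs, t(xs) %*% ys)
  eps <- ys - as.numeric(xs %*% beta)
  A <- crossprod(xs) / n
  B <- crossprod(xs * eps) / n
  omega <- solve(A) %*% B %*% solve(A)
  list(beta = as.numeric(beta), omega = omega,
       se = sqrt(diag(omega) / n))
}

# The Monte Carlo battery used by the acceptance tests is expensive; run it
# once per session and share across test blocks.
.accept_cache <- new.env(parent = emptyenv())

acceptance_battery <- function() {
  if (is.null(.accept_cache$battery)) {
    .accept_cache$battery <- run_sim_battery(
      sim_config(n = 500, reps = 100, seed = 42),
      theta_bandwidth = "ebbs")
  }
  .accept_cache$battery
}

acceptance_bound <- function() {
  if (is.null(.accept_cache$bound)) {
    .accept_cache$bound <- efficiency_bound_mc(
      sim_config(), n_outer = 2e4, n_inner = 200, seed = 42)
  }
  .accept_cache$bound
}

# Table of reference values for the two-stage design at n = 500
# (100 replications): averaged relative bias of beta-hat, empirical SE,
# estimated SE and MSE per scenario, plus the curve summaries.
reference_beta_cells <- function() {
  data.frame(
    scenario = c("naive", "ipw-true-pi", "ipw-fitted-pi", "ipw-wrong-pi",
                 "aipw-true-both", "aipw-fitted-both",
                 "aipw-wrongpi-gooddelta", "aipw-goodpi-wrongdelta",
                 "aipw-both-wrong"),
    rel_bias = c(0.120, 0.055, 0.051, 0.137, 0.041, 0.040, 0.046, 0.067,
                 0.109),
    emp_se = c(0.108, 0.140, 0.130, 0.115, 0.099, 0.099, 0.110, 0.169,
               0.125),
    est_se = c(0.102, 0.124, 0.125, 0.102, 0.101, 0.100, 0.092, 0.153,
               0.114),
    mse = c(0.070, 0.019, 0.017, 0.088, 0.010, 0.010, 0.012, 0.029,
            0.060),
    stringsAsFactors = FALSE)
}
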