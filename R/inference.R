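#' Sandwich covariance of the profile estimator of beta
#'
#' Computes the bread \eqn{\mathcal{A}_n(\hat V) = n^{-1}\sum_i
#' \hat\mu^{(1)2}_i \hat V_i^{-1}\hat x_i \hat x_i^T} with
#' \eqn{\hat x_i = x_i + \hat\varphi(Z_i)}, and the corrected meat
#' \deqn{\tilde{\mathcal{B}}_n = n^{-1}\sum_i\{\hat D_i\hat\epsilon_i -
#'   \hat C_\tau \hat I_\tau^{-1} S_i - \hat C_\eta \hat I_\eta^{-1}
#'   l_i\}^{\otimes 2},}
#' where \eqn{S_i} and \eqn{l_i} are the per-unit estimating functions of
#' the missingness and outcome working models, and the correction matrices
#' are the empirical means of \eqn{\hat D_i \partial\hat\epsilon_i/
#' \partial\tau^T} (resp. \eqn{\eta}). The correction for a nuisance model
#' that was not estimated (known selection probabilities, fixed
#' augmentation) is exactly zero. The covariance of beta-hat is
#' \eqn{\hat\Omega/n} with \eqn{\hat\Omega =
#' \mathcal{A}_n^{-1}\tilde{\mathcal{B}}_n\mathcal{A}_n^{-1}}.
#'
#' @inheritParams profile_residual
#' @return list with `bread`, `meat`, `omega` (all p x p), `se`
#'   (per-coefficient standard errors, `sqrt(diag(omega)/n)`) and `psi`
#'   (the n x p corrected influence contributions).
#' @export
sandwich_beta <- function(data, nuis, beta, theta,
                          estimator = c("aipw", "ipw", "naive"),
                          link = "identity") {
  estimator <- match.arg(estimator)
  link <- resolve_link(link)
  n <- data$n
  idx <- match(data$z, theta$z_eval)
  if (any(is.na(idx))) stop("theta curve does not cover the observed z")
  th <- theta$alpha0[idx]
  phi <- theta$phi[idx, , drop = FALSE]
  eta_lp <- as.numeric(data$x %*% beta) + th
  mu <- link$mu(eta_lp); mu1 <- link$mu1(eta_lp)
  v <- nuis$v
  r <- data$r
  y0 <- ifelse(is.na(data$y), 0, data$y)
  pi <- nuis$pi
  w_r <- r / pi
  xt <- data$x + phi

  eps <- switch(estimator,
    aipw = w_r * (y0 - mu) - (w_r - 1) * (nuis$delta - mu),
    ipw = w_r * (y0 - mu),
    naive = r * (y0 - mu))
  aw <- switch(estimator, aipw = rep(1, n), ipw = w_r, naive = as.numeric(r))

  bread <- crossprod(xt, (aw * mu1^2 / v) * xt) / n
  if (rcond(bread) < 1e-12)
    stop("singular sandwich bread (reciprocal condition number ",
         format(rcond(bread)), ")")
  D <- xt * (mu1 / v)                         # n x p
  psi <- D * eps

  miss <- nuis$miss
  if (estimator != "naive" && !is.null(miss) && !miss$known) {
    deps_dtau <- switch(estimator,
      aipw = miss$design * (-r * (y0 - nuis$delta) * (1 - pi) / pi),
      ipw = miss$design * (-r * (y0 - mu) * (1 - pi) / pi))
    C_tau <- crossprod(D, deps_dtau) / n     # p x k
    M_tau <- C_tau %*% solve(miss$dscore)
    psi <- psi - miss$score %*% t(M_tau)
  }
  out <- nuis$out
  if (estimator == "aipw" && !is.null(out) && !out$known) {
    deps_deta <- out$design * (-(w_r - 1))
    C_eta <- crossprod(D, deps_deta) / n
    M_eta <- C_eta %*% solve(out$dscore)
    psi <- psi - out$score %*% t(M_eta)
  }
  meat <- crossprod(psi) / n
  binv <- solve(bread)
  omega <- binv %*% meat %*% binv
  omega <- (omega + t(omega)) / 2
  list(bread = bread, meat = meat, omega = omega,
       se = sqrt(pmax(diag(omega), 0) / n), psi = psi)
}

#' Plug-in pointwise variance of the kernel estimator of theta
#'
#' Estimates the asymptotic pointwise variance of \eqn{\hat\theta(z)},
#' \eqn{\Sigma_\theta(z)/(nh)} with
#' \deqn{\hat\Sigma_\theta(z) = c_0(K^2)\,
#'   \widehat{E}[r(X,Z)\,\hat\epsilon^2 \mid Z=z] /
#'   \{\hat t(z)^2 \hat f_Z(z)\},}
#' where \eqn{r(X,Z) = \mu^{(1)2}V^{-2}},
#' \eqn{\hat t(z) = \widehat E[\mu^{(1)2}V^{-1}\mid Z=z]}, conditional
#' expectations are kernel averages with the same kernel and bandwidth as
#' the curve, \eqn{\hat\epsilon_i} is the per-unit estimating-equation
#' residual of the chosen branch (whose conditional second moment is the
#' bracketed variance term of the asymptotic theory), and \eqn{\hat f_Z} is
#' a kernel density estimate with Silverman's rule-of-thumb bandwidth.
#'
#' @inheritParams profile_residual
#' @param z_eval points at which to evaluate the variance.
#' @param h bandwidth used by the curve.
#' @param kernel kernel used by the curve.
#' @return numeric vector of pointwise variance estimates (nonnegative).
#' @export
theta_pointwise_variance <- function(data, nuis, beta, theta, z_eval,
                                     estimator = c("aipw", "ipw", "naive"),
                                     link = "identity",
                                     kernel = "epanechnikov", h) {
  estimator <- match.arg(estimator)
  link <- resolve_link(link)
  kernel <- resolve_kernel(kernel)
  n <- data$n
  idx <- match(data$z, theta$z_eval)
  if (any(is.na(idx))) stop("theta curve does not cover the observed z")
  eta_lp <- as.numeric(data$x %*% beta) + theta$alpha0[idx]
  mu <- link$mu(eta_lp); mu1 <- link$mu1(eta_lp)
  y0 <- ifelse(is.na(data$y), 0, data$y)
  w_r <- data$r / nuis$pi
  eps <- switch(estimator,
    aipw = w_r * (y0 - mu) - (w_r - 1) * (nuis$delta - mu),
    ipw = w_r * (y0 - mu),
    naive = data$r * (y0 - mu))
  rsq <- mu1^2 / nuis$v^2
  # local "bread": derivative weight of the local estimating equation,
  # R/pi for ipw, R for naive, 1 for aipw
  cw <- branch_pieces(data, nuis, estimator)$cweight
  tker <- cw * mu1^2 / nuis$v

  m <- length(z_eval)
  D <- outer(rep(1, m), data$z) - z_eval
  K <- kernel$k(D / h) / h
  ksum <- rowSums(K)
  if (any(ksum <= 0))
    stop("no kernel mass at some evaluation points; increase h or move ",
         "z_eval inside the support of z")
  t_hat <- as.numeric(K %*% tker) / ksum
  num <- as.numeric(K %*% (rsq * eps^2)) / ksum
  # Silverman's rule for the density of Z, same kernel family
  sdz <- stats::sd(data$z)
  iqr <- stats::IQR(data$z) / 1.34
  h_f <- 0.9 * min(sdz, if (iqr > 0) iqr else sdz) * n^(-1 / 5)
  Kf <- kernel$k(D / h_f) / h_f
  f_hat <- rowMeans(Kf)
  sigma <- kernel$c0 * num / (t_hat^2 * pmax(f_hat, 1e-12))
  out <- sigma / (n * h)
  neg <- !is.finite(out) | out < 0
  if (any(neg)) {
    warning(sum(neg), " nonpositive/undefined pointwise variance values ",
            "floored at 0")
    out[neg] <- 0
  }
  out
}

#' Monte Carlo evaluation of the semiparametric efficiency bound
#'
#' Estimates the efficiency bound for beta in the partially linear model
#' with outcomes missing at random,
#' \deqn{\mathcal{V}_{\mathrm{eff}} = E[\sigma^{-2}(X,Z)\,\mu^{(1)2}
#'   (X - \varphi_{\mathrm{eff}}(Z))(X - \varphi_{\mathrm{eff}}(Z))^T]^{-1},}
#' by nested simulation from a fully specified two-stage generating process
#' (see [sim_config()]): outer draws of (X, Z) with inner draws of
#' (U, Y, R) given (X, Z) to evaluate \eqn{\sigma^2(X,Z) =
#' \mathrm{var}(\epsilon^* \mid X, Z)}, and a local-linear kernel smooth
#' over the outer Z draws for the conditional-expectation ratio
#' \eqn{\varphi_{\mathrm{eff}}(z) = E[\mu^{(1)2}\sigma^{-2}X\mid Z=z]/
#' E[\mu^{(1)2}\sigma^{-2}\mid Z=z]}. Monte Carlo standard errors come from
#' splitting the outer sample into batches.
#'
#' @param dgp a [sim_config()] describing the generating process
#'   (identity link).
#' @param n_outer number of outer (X, Z) draws.
#' @param n_inner number of inner (U, Y, R) draws per outer draw.
#' @param seed integer seed.
#' @param h_smooth bandwidth of the conditional-expectation smooth on Z.
#' @param n_batches number of batches for the Monte Carlo standard error.
#' @return an object of class `"gplm_effbound"`: list with `v_eff` (p x p),
#'   `mc_se` (p x p), `phi_eff` (function of z), `n_outer`, `n_inner`.
#' @export
efficiency_bound_mc <- function(dgp, n_outer = 2e4, n_inner = 200,
                                seed = 1, h_smooth = 0.1, n_batches = 10) {
  stopifnot(inherits(dgp, "sim_config"))
  set.seed(seed)
  z <- stats::runif(n_outer)
  x <- stats::rnorm(n_outer, (z - 0.5)^2, 1)
  m_z <- 2 * stats::dbeta(z, 8, 8)
  # sigma^2(X, Z) by inner Monte Carlo of eps* = (R/pi) eps_Y + e(X, Z, U)
  # where e = E(eps | X, Z, U) = beta2 * U - E(beta2 * U | X, Z); the
  # marginal-model residual is eps = eps_Y + e with eps_Y ~ N(0, sigma_y^2).
  sig2 <- numeric(n_outer)
  chunk <- max(1L, floor(5e6 / n_inner))
  for (lo in seq(1L, n_outer, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_outer)
    nb <- hi - lo + 1L
    u <- matrix(stats::runif(nb * n_inner, 0, 6), nb, n_inner) +
      stats::rnorm(nb * n_inner, mean = x[lo:hi], sd = dgp$noise_sd_u) +
      stats::rnorm(nb * n_inner, mean = z[lo:hi], sd = dgp$noise_sd_u)
    pi_u <- true_pi(u, dgp)
    e_cond <- dgp$beta2 * u
    e_cond <- e_cond - rowMeans(e_cond)      # center at E[.|X,Z] estimate
    epsY <- stats::rnorm(nb * n_inner, 0, dgp$sigma_y)
    rr <- stats::rbinom(nb * n_inner, 1, as.numeric(pi_u))
    eps_star <- matrix(rr / as.numeric(pi_u) * epsY, nb, n_inner) + e_cond
    mns <- rowMeans(eps_star)
    sig2[lo:hi] <- rowSums((eps_star - mns)^2) / (n_inner - 1)
  }
  # identity link: mu1 = 1. The (1 - 2/df) factor removes the leading
  # Jensen bias of inverting a finite-inner-sample variance estimate
  # (exact for Gaussian residuals, a good approximation here).
  w <- (1 - 2 / (n_inner - 1)) / sig2
  # phi_eff(z): local-linear smooths of w*x and w on a z grid
  z_gr <- seq(min(z), max(z), length.out = 201)
  sm <- ll_smooth(z, z_gr, h_smooth, make_kernel("epanechnikov"),
                  rep(1, n_outer), cbind(w * x, w), slope = FALSE)
  phi_gr <- sm$a0[, 1] / sm$a0[, 2]
  phi_eff_at <- stats::approx(z_gr, phi_gr, xout = z, rule = 2)$y
  contrib <- w * (x - phi_eff_at)^2
  info <- mean(contrib)
  v_eff <- 1 / info
  batch <- split(contrib, rep(seq_len(n_batches), length.out = n_outer))
  b_means <- vapply(batch, mean, numeric(1))
  info_se <- stats::sd(b_means) / sqrt(n_batches)
  mc_se <- info_se / info^2                  # delta method for 1/info
  structure(list(v_eff = matrix(v_eff, 1, 1),
                 mc_se = matrix(mc_se, 1, 1),
                 phi_eff = stats::approxfun(z_gr, phi_gr, rule = 2),
                 n_outer = n_outer, n_inner = n_inner, seed = seed),
            class = "gplm_effbound")
}

#' @export
print.gplm_effbound <- function(x, ...) {
  cat("Semiparametric efficiency bound (Monte Carlo)\n")
  cat(sprintf("  V_eff = %.4f  (MC SE %.4f; %d outer x %d inner draws)\n",
              x$v_eff[1, 1], x$mc_se[1, 1], x$n_outer, x$n_inner))
  invisible(x)
}
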