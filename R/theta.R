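#' Minimal nuisance bundle for the kernel and profile stages
#'
#' The estimating-equation stages need, per unit: a selection probability
#' `pi`, an augmentation value `delta` (AIPW only) and a working variance
#' `v`. [gplm()] assembles this bundle from fitted nuisance models; this
#' constructor builds one directly from known quantities, which is the
#' natural entry point in designed two-stage studies and in simulations
#' where the true selection probabilities and conditional means are
#' available.
#'
#' @param pi selection probabilities, scalar or length-n vector in (0, 1].
#' @param delta augmentation values E(Y|X,Z,U), length-n vector or `NULL`.
#' @param v working variances, scalar or length-n positive vector.
#' @param n number of units (needed when all arguments are scalars).
#' @return an object of class `"gplm_nuisance"` with fields `pi`, `delta`,
#'   `v`, and `NULL` placeholders for the fitted model components
#'   (`miss`, `out`, `var`).
#' @export
gplm_nuisance <- function(pi, delta = NULL, v = 1,
                          n = max(length(pi), length(delta), length(v))) {
  pi <- rep_len(as.numeric(pi), n)
  if (any(pi <= 0 | pi > 1)) stop("pi must lie in (0, 1]")
  v <- rep_len(as.numeric(v), n)
  if (any(v <= 0)) stop("working variances must be positive")
  if (!is.null(delta)) delta <- rep_len(as.numeric(delta), n)
  structure(list(pi = pi, delta = delta, v = v,
                 miss = NULL, out = NULL, var = NULL),
            class = "gplm_nuisance")
}

#' Numerical controls for the kernel-profile fit
#'
#' @param tol convergence tolerance on the outer beta iteration (sup-norm
#'   of successive beta iterates) and on the profile estimating-equation
#'   norm.
#' @param max_outer_iter cap on outer (theta, beta) sweeps.
#' @param local_tol tolerance on the local (2-dimensional) kernel
#'   estimating-equation norm.
#' @param local_max_iter cap on damped-Newton iterations per local solve.
#' @param pi_floor truncation level for small fitted selection
#'   probabilities.
#' @param init_sweeps number of kernel/profile sweeps in the initial
#'   estimator.
#' @param zeta_init fixed working-variance constant used by the initial
#'   estimator.
#' @param zeta_refresh logical: re-estimate the working variance at every
#'   outer sweep instead of once from the initial fit (the asymptotics do
#'   not depend on the working variance, so the default is off).
#' @param grid_size number of curve evaluation points added to the observed
#'   z values for reporting and plotting.
#' @return a list of class `"gplm_control"`.
#' @export
gplm_control <- function(tol = 1e-6, max_outer_iter = 50,
                         local_tol = 1e-8, local_max_iter = 50,
                         pi_floor = 0.01, init_sweeps = 2, zeta_init = 1,
                         zeta_refresh = FALSE, grid_size = 101) {
  stopifnot(tol > 0, local_tol > 0, max_outer_iter >= 1,
            local_max_iter >= 1, pi_floor >= 0, pi_floor < 0.5,
            init_sweeps >= 1, zeta_init > 0, grid_size >= 2)
  structure(list(tol = tol, max_outer_iter = max_outer_iter,
                 local_tol = local_tol, local_max_iter = local_max_iter,
                 pi_floor = pi_floor, init_sweeps = init_sweeps,
                 zeta_init = zeta_init, zeta_refresh = zeta_refresh,
                 grid_size = grid_size),
            class = "gplm_control")
}

resolve_link <- function(link) {
  if (inherits(link, "gplm_link")) link else make_link(link)
}
resolve_kernel <- function(kernel) {
  if (inherits(kernel, "gplm_kernel")) kernel else make_kernel(kernel)
}

# Weighted local-linear smoother applied to the columns of Y: returns the
# local intercepts (a0 = L0 %*% Y) and, optionally, local slopes
# (a1 = L1 %*% Y) at each evaluation point. Row-chunked so the kernel
# matrix never exceeds a few million entries.
ll_smooth <- function(z_obs, z_eval, h, kernel, w, Y, slope = TRUE) {
  n <- length(z_obs)
  m <- length(z_eval)
  Y <- as.matrix(Y)
  a0 <- matrix(NA_real_, m, ncol(Y))
  a1 <- if (slope) matrix(NA_real_, m, ncol(Y)) else NULL
  chunk <- max(1L, floor(4e6 / n))
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    mb <- hi - lo + 1L
    D <- outer(rep(1, mb), z_obs) - z_eval[lo:hi]  # D[i, j] = z_j - z0_i
    K <- kernel$k(D / h) / h
    W <- K * rep(w, each = mb)
    if (any(rowSums(W > 0) < 2L))
      stop("fewer than 2 units carry kernel weight at some evaluation ",
           "points; increase the bandwidth h")
    s0 <- rowSums(W)
    s1 <- rowSums(W * D)
    s2 <- rowSums(W * D * D)
    den <- s0 * s2 - s1^2
    if (any(den <= .Machine$double.eps * (s0 * s2 + s1^2 + 1e-300)))
      stop("singular local system (all z equal within some window); ",
           "increase the bandwidth h")
    a0[lo:hi, ] <- (W * (s2 - D * s1) / den) %*% Y
    if (slope) a1[lo:hi, ] <- (W * (s0 * D - s1) / den) %*% Y
  }
  list(a0 = a0, a1 = a1)
}

# Per-unit pseudo-outcome and estimating-equation pieces shared by the
# kernel and profile stages.
branch_pieces <- function(data, nuis, estimator) {
  r <- data$r
  y0 <- ifelse(is.na(data$y), 0, data$y)
  w_r <- r / nuis$pi
  switch(estimator,
    aipw = {
      if (is.null(nuis$delta))
        stop("AIPW estimation requires augmentation values 'delta'")
      list(ystar = w_r * y0 - (w_r - 1) * nuis$delta, cweight = rep(1, data$n))
    },
    ipw = list(ystar = y0, cweight = w_r),
    naive = list(ystar = y0, cweight = as.numeric(r)),
    stop("unknown estimator '", estimator, "'"))
}

#' Solve one local AIPW/IPW/naive kernel estimating equation
#'
#' At a point `z0`, solves the two-dimensional local-linear kernel
#' estimating equation in \eqn{\alpha = (\alpha_0, \alpha_1)} by damped
#' Newton iteration with the analytic Jacobian. For the AIPW branch the
#' estimating function is
#' \deqn{\sum_i K_h(Z_i - z_0)\, \mu^{(1)}_i V_i^{-1}
#'   \mathcal{G}(Z_i - z_0)\{R_i\hat\pi_i^{-1}(Y_i - \mu_i) -
#'   (R_i\hat\pi_i^{-1} - 1)(\hat\delta_i - \mu_i)\}}
#' with \eqn{\mu_i = \mu(x_i^T\beta + \alpha_0 + \alpha_1 (Z_i - z_0))} and
#' \eqn{\mathcal{G}(u) = (1, u)^T}; the IPW branch drops the augmentation
#' and weights by \eqn{R_i/\hat\pi_i}, the naive branch restricts to
#' complete cases unweighted. For the identity link the equation is linear
#' in \eqn{\alpha} and one Newton step returns the exact generalized
#' least-squares solution.
#'
#' @param data a [observed_data()] object.
#' @param nuis a [gplm_nuisance()] bundle.
#' @param beta coefficient vector (length p).
#' @param z0 scalar evaluation point.
#' @param h positive bandwidth.
#' @param estimator `"aipw"`, `"ipw"` or `"naive"`.
#' @param link,kernel link and kernel, as names or objects.
#' @param control a [gplm_control()] list.
#' @param alpha_init optional starting value (length 2).
#' @return list with `alpha` (length 2), `converged` (logical) and
#'   `norm` (final estimating-equation norm).
#' @export
solve_local <- function(data, nuis, beta, z0, h,
                        estimator = c("aipw", "ipw", "naive"),
                        link = "identity", kernel = "epanechnikov",
                        control = gplm_control(), alpha_init = NULL) {
  estimator <- match.arg(estimator)
  link <- resolve_link(link)
  kernel <- resolve_kernel(kernel)
  k_all <- kernel_weights(data$z, z0, h, kernel)
  idx <- which(k_all > 0)
  if (length(idx) < 2L)
    stop("fewer than 2 units carry kernel weight at z0 = ", z0,
         "; increase the bandwidth h")
  if (estimator %in% c("ipw", "naive") && sum(data$r[idx]) < 2L)
    stop("fewer than 2 complete cases in the window at z0 = ", z0,
         "; increase the bandwidth h")
  pieces <- branch_pieces(data, nuis, estimator)
  k <- k_all[idx]
  v <- nuis$v[idx]
  x <- data$x[idx, , drop = FALSE]
  dz <- data$z[idx] - z0
  r <- data$r[idx]
  y0 <- ifelse(is.na(data$y[idx]), 0, data$y[idx])
  w_r <- r / nuis$pi[idx]
  delta <- nuis$delta[idx]
  cw <- pieces$cweight[idx]
  xb <- as.numeric(x %*% beta)
  G <- cbind(1, dz)
  kv <- k / v

  ee <- function(alpha) {
    eta <- xb + alpha[1] + alpha[2] * dz
    mu <- link$mu(eta); mu1 <- link$mu1(eta)
    b <- switch(estimator,
      aipw = w_r * (y0 - mu) - (w_r - 1) * (delta - mu),
      ipw = w_r * (y0 - mu),
      naive = r * (y0 - mu))
    list(F = crossprod(G, kv * mu1 * b), mu = mu, mu1 = mu1, b = b, eta = eta)
  }
  jac <- function(st) {
    mu2 <- link$mu2(st$eta)
    crossprod(G, (kv * (mu2 * st$b - st$mu1^2 * cw)) * G)
  }

  alpha <- if (is.null(alpha_init)) {
    # start from a local mean on the link scale: mu(mean(xb) + a0) ~ ybar
    wts <- k * pmax(cw, 0) / v
    ybar <- sum(wts * pieces$ystar[idx]) / max(sum(wts), 1e-300)
    a0 <- switch(link$name,
      identity = ybar,
      logit = stats::qlogis(min(max(ybar, 1e-3), 1 - 1e-3)),
      log = log(max(ybar, 1e-3)))
    c(a0 - stats::weighted.mean(xb, wts + 1e-300), 0)
  } else alpha_init
  st <- ee(alpha)
  nrm <- sqrt(sum(st$F^2))
  converged <- nrm <= control$local_tol
  it <- 0L
  while (!converged && it < control$local_max_iter) {
    it <- it + 1L
    J <- jac(st)
    step <- tryCatch(solve(J, st$F),
                     error = function(e)
                       stop("singular local Jacobian at z0 = ", z0,
                            "; increase the bandwidth h"))
    lam <- 1
    repeat {
      cand <- alpha - lam * as.numeric(step)
      st_new <- ee(cand)
      nrm_new <- sqrt(sum(st_new$F^2))
      if (nrm_new < nrm || lam < 1e-4) break
      lam <- lam / 2
    }
    alpha <- cand; st <- st_new; nrm <- nrm_new
    converged <- nrm <= control$local_tol
  }
  list(alpha = as.numeric(alpha), converged = converged, norm = nrm)
}

#' Estimate the smooth component theta(., beta) on a grid
#'
#' Profiles the nonparametric component: for fixed `beta`, solves the local
#' kernel estimating equation at every evaluation point (always including
#' the observed z values, which the profile equation for beta needs) and
#' computes the derivative matrix \eqn{\hat\varphi(z,\beta) =
#' \partial\hat\theta(z,\beta)/\partial\beta} by implicit differentiation.
#' For the identity link with per-unit constant working variances the whole
#' curve is the exact closed-form local-linear smoother applied to the
#' AIPW/IPW/naive pseudo-outcome.
#'
#' @inheritParams solve_local
#' @param z_eval evaluation points; `NULL` for the observed z plus an
#'   equispaced grid of `control$grid_size` points between the 5% and 95%
#'   quantiles of z.
#' @param phi logical: also compute the beta-derivative matrix.
#' @return an object of class `"gplm_theta"`: list with `z_eval`, `alpha0`
#'   (theta-hat), `alpha1` (local slope), `phi` (m x p matrix or NULL),
#'   `converged` (logical vector), `h`, `estimator`, `beta`.
#' @export
theta_curve <- function(data, nuis, beta, z_eval = NULL, h,
                        estimator = c("aipw", "ipw", "naive"),
                        link = "identity", kernel = "epanechnikov",
                        control = gplm_control(), phi = TRUE) {
  estimator <- match.arg(estimator)
  link <- resolve_link(link)
  kernel <- resolve_kernel(kernel)
  if (is.null(z_eval)) {
    qs <- stats::quantile(data$z, c(0.05, 0.95), names = FALSE)
    z_eval <- sort(unique(c(data$z, seq(qs[1], qs[2],
                                        length.out = control$grid_size))))
  }
  rng <- range(data$z)
  if (any(z_eval < rng[1] - h) || any(z_eval > rng[2] + h))
    stop("evaluation points outside the observed range of z")
  m <- length(z_eval)
  p <- data$p
  pieces <- branch_pieces(data, nuis, estimator)

  if (link$name == "identity") {
    w <- pieces$cweight / nuis$v
    resp <- pieces$ystar - as.numeric(data$x %*% beta)
    sm <- ll_smooth(data$z, z_eval, h, kernel, w,
                    cbind(resp, if (phi) data$x))
    alpha0 <- sm$a0[, 1]
    alpha1 <- sm$a1[, 1]
    phimat <- if (phi) -sm$a0[, -1, drop = FALSE] else NULL
    conv <- rep(TRUE, m)
  } else {
    alpha0 <- alpha1 <- numeric(m)
    conv <- logical(m)
    ord <- order(z_eval)
    warm <- NULL
    for (i in ord) {
      sol <- solve_local(data, nuis, beta, z_eval[i], h, estimator,
                         link, kernel, control, alpha_init = warm)
      alpha0[i] <- sol$alpha[1]
      alpha1[i] <- sol$alpha[2]
      conv[i] <- sol$converged
      warm <- sol$alpha
    }
    phimat <- NULL
  }
  out <- structure(list(z_eval = z_eval, alpha0 = alpha0, alpha1 = alpha1,
                        phi = phimat, converged = conv, h = h,
                        estimator = estimator, beta = beta,
                        link = link$name, kernel = kernel$name),
                   class = "gplm_theta")
  if (phi && is.null(out$phi))
    out$phi <- phi_derivative(data, nuis, beta, out, estimator, link,
                              kernel, control)
  out
}

#' Derivative of the profiled curve with respect to beta
#'
#' Computes \eqn{\hat\varphi(z, \beta) = \partial\hat\theta(z,\beta)/
#' \partial\beta} at every evaluation point of a solved curve. The default
#' differentiates the local estimating equation implicitly: with
#' \eqn{J_\alpha} and \eqn{J_\beta} the analytic Jacobians of the local
#' estimating function at its root, \eqn{\partial\hat\alpha/\partial\beta =
#' -J_\alpha^{-1} J_\beta}, and \eqn{\hat\varphi} is its first row. A
#' central finite-difference of \eqn{\hat\theta(z, \beta \pm \epsilon e_j)}
#' is available for cross-checking.
#'
#' @inheritParams theta_curve
#' @param theta a solved [theta_curve()] object at the same `beta`.
#' @param method `"analytic"` (implicit differentiation) or `"fd"`.
#' @param fd_step base step for the finite-difference method.
#' @return numeric matrix (length(z_eval) x p).
#' @export
phi_derivative <- function(data, nuis, beta, theta,
                           estimator = c("aipw", "ipw", "naive"),
                           link = "identity", kernel = "epanechnikov",
                           control = gplm_control(),
                           method = c("analytic", "fd"), fd_step = 1e-5) {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  link <- resolve_link(link)
  kernel <- resolve_kernel(kernel)
  m <- length(theta$z_eval)
  p <- data$p
  if (method == "fd") {
    out <- matrix(NA_real_, m, p)
    for (j in seq_len(p)) {
      step <- fd_step * (1 + abs(beta[j]))
      bp <- beta; bp[j] <- bp[j] + step
      bm <- beta; bm[j] <- bm[j] - step
      tp <- theta_curve(data, nuis, bp, theta$z_eval, theta$h, estimator,
                        link, kernel, control, phi = FALSE)
      tm <- theta_curve(data, nuis, bm, theta$z_eval, theta$h, estimator,
                        link, kernel, control, phi = FALSE)
      out[, j] <- (tp$alpha0 - tm$alpha0) / (2 * step)
    }
    return(out)
  }
  pieces <- branch_pieces(data, nuis, estimator)
  if (link$name == "identity") {
    sm <- ll_smooth(data$z, theta$z_eval, theta$h, kernel,
                    pieces$cweight / nuis$v, data$x, slope = FALSE)
    return(-sm$a0)
  }
  y0 <- ifelse(is.na(data$y), 0, data$y)
  w_r <- data$r / nuis$pi
  out <- matrix(NA_real_, m, p)
  for (i in seq_len(m)) {
    z0 <- theta$z_eval[i]
    k_all <- kernel_weights(data$z, z0, theta$h, kernel)
    idx <- which(k_all > 0)
    dz <- data$z[idx] - z0
    G <- cbind(1, dz)
    x <- data$x[idx, , drop = FALSE]
    kv <- k_all[idx] / nuis$v[idx]
    eta <- as.numeric(x %*% beta) + theta$alpha0[i] + theta$alpha1[i] * dz
    mu <- link$mu(eta); mu1 <- link$mu1(eta); mu2 <- link$mu2(eta)
    b <- switch(estimator,
      aipw = w_r[idx] * (y0[idx] - mu) -
             (w_r[idx] - 1) * (nuis$delta[idx] - mu),
      ipw = w_r[idx] * (y0[idx] - mu),
      naive = data$r[idx] * (y0[idx] - mu))
    cw <- pieces$cweight[idx]
    core <- kv * (mu2 * b - mu1^2 * cw)
    J_alpha <- crossprod(G, core * G)
    J_beta <- crossprod(G, core * x)
    dab <- tryCatch(-solve(J_alpha, J_beta),
                    error = function(e)
                      stop("singular local Jacobian at z0 = ", z0,
                           "; increase the bandwidth h"))
    out[i, ] <- dab[1, ]
  }
  out
}
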