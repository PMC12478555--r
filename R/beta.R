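#' Value of the profile estimating function for beta
#'
#' Evaluates (at a given `beta`, with the curve `theta` profiled at that
#' same `beta`) the AIPW profile estimating function
#' \deqn{n^{-1}\sum_i \tilde\mu^{(1)}_i V_i^{-1}
#'   \{x_i + \partial\hat\theta(Z_i,\beta)/\partial\beta\}
#'   \{R_i\hat\pi_i^{-1}(Y_i - \tilde\mu_i) -
#'     (R_i\hat\pi_i^{-1} - 1)(\hat\delta_i - \tilde\mu_i)\}}
#' with \eqn{\tilde\mu_i = \mu(x_i^T\beta + \hat\theta(Z_i, \beta))}, or its
#' IPW / naive counterpart. The fitted `beta` is the root of this function.
#'
#' @inheritParams theta_curve
#' @param theta a [theta_curve()] object solved at `beta` whose evaluation
#'   points contain all observed z values and whose `phi` is filled.
#' @return numeric vector of length p (mean-scaled estimating function).
#' @export
profile_residual <- function(data, nuis, beta, theta,
                             estimator = c("aipw", "ipw", "naive"),
                             link = "identity") {
  estimator <- match.arg(estimator)
  link <- resolve_link(link)
  idx <- match(data$z, theta$z_eval)
  if (any(is.na(idx)))
    stop("theta curve is missing evaluation points at some observed z")
  if (is.null(theta$phi))
    stop("theta curve must carry the phi derivative matrix")
  th <- theta$alpha0[idx]
  phi <- theta$phi[idx, , drop = FALSE]
  eta <- as.numeric(data$x %*% beta) + th
  mu <- link$mu(eta); mu1 <- link$mu1(eta)
  y0 <- ifelse(is.na(data$y), 0, data$y)
  w_r <- data$r / nuis$pi
  b <- switch(estimator,
    aipw = w_r * (y0 - mu) - (w_r - 1) * (nuis$delta - mu),
    ipw = w_r * (y0 - mu),
    naive = data$r * (y0 - mu))
  xt <- data$x + phi
  as.numeric(crossprod(xt, (mu1 / nuis$v) * b)) / data$n
}

#' Solve the profile estimating equation for beta
#'
#' Damped Newton iteration on the profile estimating function, with the
#' Jacobian obtained by finite differences of [profile_residual()] under
#' re-profiling: every trial `beta` re-solves the curve
#' \eqn{\hat\theta(\cdot, \beta)} (and its derivative \eqn{\hat\varphi}) at
#' the observed z values, so the chain rule through the profiled curve is
#' captured exactly.
#'
#' @inheritParams theta_curve
#' @param beta_init numeric starting value (length p).
#' @return list with `beta`, `converged`, `norm` (final residual norm) and
#'   `iter`.
#' @export
solve_beta <- function(data, nuis, beta_init, h,
                       estimator = c("aipw", "ipw", "naive"),
                       link = "identity", kernel = "epanechnikov",
                       control = gplm_control()) {
  estimator <- match.arg(estimator)
  link <- resolve_link(link)
  kernel <- resolve_kernel(kernel)
  z_obs <- sort(unique(data$z))
  res_at <- function(b) {
    th <- theta_curve(data, nuis, b, z_obs, h, estimator, link, kernel,
                      control, phi = TRUE)
    profile_residual(data, nuis, b, th, estimator, link)
  }
  beta <- as.numeric(beta_init)
  p <- length(beta)
  Fv <- res_at(beta)
  nrm <- sqrt(sum(Fv^2))
  it <- 0L
  while (nrm > control$tol && it < control$max_outer_iter) {
    it <- it + 1L
    J <- matrix(NA_real_, p, p)
    for (j in seq_len(p)) {
      stepj <- 1e-6 * (1 + abs(beta[j]))
      bp <- beta; bp[j] <- bp[j] + stepj
      J[, j] <- (res_at(bp) - Fv) / stepj
    }
    dir <- tryCatch(solve(J, Fv), error = function(e)
      stop("singular profile Jacobian at beta = ",
           paste(signif(beta, 4), collapse = ", ")))
    lam <- 1
    repeat {
      cand <- beta - lam * as.numeric(dir)
      Fc <- res_at(cand)
      nc <- sqrt(sum(Fc^2))
      if (nc < nrm || lam < 1e-4) break
      lam <- lam / 2
    }
    beta <- cand; Fv <- Fc; nrm <- nc
  }
  list(beta = beta, converged = nrm <= control$tol, norm = nrm, iter = it)
}

#' Root-n-consistent initial estimator
#'
#' Seeds the outer iteration with a complete-case inverse-probability
#' weighted kernel-profile fit that fixes the working variance at the
#' user-specified constant `control$zeta_init` (no variance update). For the
#' identity link the IPW fit is closed form and one pass is exact; otherwise
#' a small fixed number of kernel/profile sweeps (`control$init_sweeps`) is
#' run from beta = 0.
#'
#' @inheritParams theta_curve
#' @param pi selection probabilities (length n), known or fitted.
#' @return list with `beta_check` (length p) and `theta_check` (length n,
#'   the curve at the observed z).
#' @export
initial_fit <- function(data, pi, h, link = "identity",
                        kernel = "epanechnikov", control = gplm_control()) {
  link <- resolve_link(link)
  kernel <- resolve_kernel(kernel)
  nuis <- gplm_nuisance(pi = pi, v = control$zeta_init, n = data$n)
  if (link$name == "identity") {
    cf <- closed_form_fit(data, nuis, "ipw", h, kernel,
                          z_extra = numeric(0))
    idx <- match(data$z, cf$z_eval)
    return(list(beta_check = cf$beta, theta_check = cf$alpha0[idx]))
  }
  beta <- rep(0, data$p)
  z_obs <- sort(unique(data$z))
  for (s in seq_len(control$init_sweeps)) {
    sol <- solve_beta(data, nuis, beta, h, "ipw", link, kernel, control)
    beta <- sol$beta
  }
  th <- theta_curve(data, nuis, beta, z_obs, h, "ipw", link, kernel,
                    control, phi = FALSE)
  list(beta_check = beta,
       theta_check = th$alpha0[match(data$z, th$z_eval)])
}

# Exact closed-form kernel-profile fit: identity link, per-unit working
# variances held fixed. Both stages are linear in the pseudo-outcome, so
# beta-hat is the profile least-squares solution on smoother-residualized
# covariates and theta-hat is the local-linear smooth of the residual.
closed_form_fit <- function(data, nuis, estimator, h, kernel,
                            z_extra = numeric(0)) {
  pieces <- branch_pieces(data, nuis, estimator)
  z_eval <- sort(unique(c(data$z, z_extra)))
  p <- data$p
  wv <- pieces$cweight / nuis$v
  # one smoothing pass over (X, ystar); the profiled curve at any beta is
  # smooth(ystar) - smooth(X) beta by linearity
  sm <- ll_smooth(data$z, z_eval, h, kernel, wv,
                  cbind(data$x, pieces$ystar))
  idx <- match(data$z, z_eval)
  xs <- data$x - sm$a0[idx, seq_len(p), drop = FALSE]      # X-tilde
  ys <- pieces$ystar - sm$a0[idx, p + 1]
  A <- crossprod(xs, wv * xs)
  if (rcond(A) < 1e-12)
    stop("singular profile system (condition ", format(rcond(A)),
         "); covariates may be collinear after smoothing")
  beta <- as.numeric(solve(A, crossprod(xs, wv * ys)))
  list(beta = beta,
       z_eval = z_eval,
       alpha0 = sm$a0[, p + 1] - as.numeric(
         sm$a0[, seq_len(p), drop = FALSE] %*% beta),
       alpha1 = sm$a1[, p + 1] - as.numeric(
         sm$a1[, seq_len(p), drop = FALSE] %*% beta),
       phi = -sm$a0[, seq_len(p), drop = FALSE])
}

#' Fit a generalized partially linear model with missing outcomes
#'
#' The computational engine behind [gplm()]: runs the full kernel-profile
#' algorithm on an assembled [observed_data()] object with explicit design
#' matrices for the nuisance models. The algorithm is: fit the missingness
#' and outcome working models; compute the initial IPW estimator with unit
#' working variance; estimate the working-variance parameter from the
#' squared residuals of the initial fit; then alternate the kernel stage
#' (curve at the current beta) and the profile stage (beta update) until the
#' beta iterates stabilize. For the identity link with the constant variance
#' family the alternation has an exact closed form and a single pass is
#' performed. At convergence the sandwich covariance of beta-hat and the
#' plug-in pointwise variance of theta-hat are computed.
#'
#' @inheritParams theta_curve
#' @param pi_design design matrix for the logistic missingness model;
#'   ignored if `pi_known` is given. Either must be supplied unless
#'   `estimator = "naive"`.
#' @param pi_known known selection probabilities (scalar or length n).
#' @param delta_design design matrix for the outcome working model (AIPW).
#' @param delta_fixed fixed augmentation values E(Y|X,Z,U) (AIPW),
#'   overriding `delta_design`.
#' @param delta_weights optional weights for the outcome-model fit
#'   (`"ipw"` for 1/pi-hat, or a numeric vector).
#' @param variance working-variance family, `"constant"` or `"loglinear"`.
#' @param se logical: compute sandwich and pointwise variances.
#' @param z_grid reporting grid for the curve and its pointwise variance;
#'   defaults to `control$grid_size` equispaced points between the 5% and
#'   95% quantiles of z.
#' @return an object of class `"gplm"`; see [gplm()] for its contents.
#' @export
gplm_fit <- function(data, estimator = c("aipw", "ipw", "naive"), h,
                     pi_design = NULL, pi_known = NULL,
                     delta_design = NULL, delta_fixed = NULL,
                     delta_weights = NULL,
                     link = "identity", kernel = "epanechnikov",
                     variance = c("constant", "loglinear"),
                     control = gplm_control(), se = TRUE, z_grid = NULL) {
  stopifnot(inherits(data, "gplm_data"))
  estimator <- match.arg(estimator)
  variance <- match.arg(variance)
  link <- resolve_link(link)
  kernel <- resolve_kernel(kernel)
  if (!is.numeric(h) || h <= 0) stop("'h' must be a positive bandwidth")

  ## --- nuisance models -----------------------------------------------
  miss <- if (estimator == "naive") {
    fit_missingness(data, known = 1)
  } else if (!is.null(pi_known)) {
    fit_missingness(data, known = pi_known, pi_floor = control$pi_floor)
  } else if (!is.null(pi_design)) {
    fit_missingness(data, design = pi_design, pi_floor = control$pi_floor)
  } else {
    stop("estimator '", estimator, "' needs 'pi_design' or 'pi_known'")
  }
  out <- NULL
  if (estimator == "aipw") {
    if (!is.null(delta_fixed)) {
      out <- fit_outcome_model(data, fixed = delta_fixed)
    } else if (!is.null(delta_design)) {
      wts <- delta_weights
      if (identical(wts, "ipw")) wts <- 1 / miss$pi
      out <- fit_outcome_model(data, design = delta_design, weights = wts)
    } else {
      stop("AIPW estimation needs 'delta_design' or 'delta_fixed'")
    }
  }

  ## --- initial estimator and working variance ------------------------
  init <- initial_fit(data, miss$pi, h, link, kernel, control)
  lp0 <- as.numeric(data$x %*% init$beta_check) + init$theta_check
  q0 <- link$mu(lp0)
  varfit <- fit_working_variance(data, miss$pi, out$delta, q0,
                                 family = variance,
                                 ipw = (estimator != "aipw"), lp = lp0)
  nuis <- gplm_nuisance(pi = miss$pi, delta = out$delta,
                        v = varfit$v_of(lp0), n = data$n)
  nuis$miss <- miss; nuis$out <- out; nuis$var <- varfit

  ## --- evaluation points ----------------------------------------------
  if (is.null(z_grid)) {
    qs <- stats::quantile(data$z, c(0.05, 0.95), names = FALSE)
    z_grid <- seq(qs[1], qs[2], length.out = control$grid_size)
  }

  ## --- solve ----------------------------------------------------------
  closed <- link$name == "identity" && varfit$family == "constant"
  if (closed) {
    cf <- closed_form_fit(data, nuis, estimator, h, kernel, z_extra = z_grid)
    beta <- cf$beta
    theta <- structure(list(z_eval = cf$z_eval, alpha0 = cf$alpha0,
                            alpha1 = cf$alpha1, phi = cf$phi,
                            converged = rep(TRUE, length(cf$z_eval)),
                            h = h, estimator = estimator, beta = beta,
                            link = link$name, kernel = kernel$name),
                       class = "gplm_theta")
    n_outer <- 1L
    converged <- TRUE
  } else {
    beta <- init$beta_check
    n_outer <- 0L
    converged <- FALSE
    while (n_outer < control$max_outer_iter) {
      n_outer <- n_outer + 1L
      if (control$zeta_refresh && n_outer > 1L) {
        th_tmp <- theta_curve(data, nuis, beta, sort(unique(data$z)), h,
                              estimator, link, kernel, control, phi = FALSE)
        lp <- as.numeric(data$x %*% beta) +
          th_tmp$alpha0[match(data$z, th_tmp$z_eval)]
        varfit <- fit_working_variance(data, miss$pi, out$delta,
                                       link$mu(lp), family = variance,
                                       ipw = (estimator != "aipw"), lp = lp)
        nuis$v <- varfit$v_of(lp)
        nuis$var <- varfit
      }
      sol <- solve_beta(data, nuis, beta, h, estimator, link, kernel,
                        control)
      delta_beta <- max(abs(sol$beta - beta))
      beta <- sol$beta
      if (sol$converged && delta_beta <= control$tol) {
        converged <- TRUE
        break
      }
    }
    theta <- theta_curve(data, nuis, beta,
                         sort(unique(c(data$z, z_grid))), h, estimator,
                         link, kernel, control, phi = TRUE)
  }

  fit <- structure(list(beta = beta, theta = theta, nuis = nuis,
                        estimator = estimator, h = h,
                        link = link, kernel = kernel,
                        variance = varfit$family,
                        control = control, data = data,
                        z_grid = z_grid, n_outer = n_outer,
                        converged = converged,
                        beta_init = init$beta_check),
                   class = "gplm")
  if (se) {
    sw <- sandwich_beta(data, nuis, beta, theta, estimator, link)
    fit$bread <- sw$bread
    fit$meat <- sw$meat
    fit$omega <- sw$omega
    fit$vcov <- sw$omega / data$n
    fit$se <- sw$se
    fit$theta_var_grid <- theta_pointwise_variance(
      data, nuis, beta, theta, z_grid, estimator, link, kernel, h)
  }
  fit
}
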