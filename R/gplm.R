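#' Generalized partially linear regression with missing outcomes
#'
#' Fits \eqn{E(Y|X,Z) = \mu(X^T\beta + \theta(Z))} — a known monotone link
#' \eqn{\mu}, a parametric index in the primary covariates X and an unknown
#' smooth function of a scalar covariate Z — when the outcome is missing at
#' random given (X, Z) and auxiliary covariates U:
#' \eqn{\Pr(R=1|X,Z,U,Y) = \Pr(R=1|X,Z,U)}. Three estimators are
#' available:
#' \describe{
#'   \item{`"aipw"`}{augmented inverse probability weighting: complete
#'     cases weighted by the inverse estimated (or known) selection
#'     probability plus an augmentation term built from a working model
#'     for E(Y|X,Z,U). Doubly robust — consistent if either the selection
#'     model or the outcome working model is correct — and locally
#'     semiparametric efficient when both are.}
#'   \item{`"ipw"`}{inverse probability weighting only; consistent when
#'     the selection model is correct.}
#'   \item{`"naive"`}{unweighted complete-case analysis; biased when
#'     selection depends on variables related to the outcome.}
#' }
#' \eqn{\theta} is estimated by local-linear kernel estimating equations
#' and \eqn{\beta} by the corresponding profile estimating equation, with a
#' sandwich variance that accounts for the estimated nuisance models.
#'
#' @param formula two-sided formula for the parametric part,
#'   `y ~ x1 + x2 + ...`. No intercept is fitted: the level of the model
#'   is absorbed by theta.
#' @param nonpar one-sided formula naming the single smoothing covariate,
#'   e.g. `~ z`.
#' @param data a data frame containing all variables. Missing outcomes are
#'   `NA`; the response indicator is derived from them.
#' @param aux optional one-sided formula naming auxiliary covariates used
#'   by the default nuisance models.
#' @param estimator `"aipw"` (default), `"ipw"` or `"naive"`.
#' @param pi_formula one-sided formula for the logistic selection model
#'   (default: linear in the parametric covariates, the smoothing
#'   covariate and the auxiliaries).
#' @param pi_known optional known selection probabilities (scalar or
#'   length n), as in a designed two-stage study; overrides `pi_formula`.
#' @param delta_formula one-sided formula for the outcome working model
#'   E(Y|X,Z,U) fitted by least squares on the complete cases (same
#'   default as `pi_formula`).
#' @param delta_fixed optional fixed augmentation values (length n);
#'   overrides `delta_formula`.
#' @param delta_weights `NULL` for an unweighted outcome-model fit,
#'   `"ipw"` for weights 1/pi-hat, or a numeric vector.
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @param kernel `"epanechnikov"` or `"gaussian"`.
#' @param bandwidth positive bandwidth for the kernel stage, or `"ebbs"`
#'   for empirical-bias bandwidth selection ([ebbs_select()], using the
#'   initial inverse-probability-weighted fit).
#' @param variance working-variance family: `"constant"` or `"loglinear"`.
#' @param control a [gplm_control()] list.
#' @return an object of class `"gplm"` with components `beta` (named
#'   coefficients), `se`, `vcov`, `bread`, `meat`, `theta` (the fitted
#'   curve object), `theta_var_grid` and `z_grid` (pointwise variance on
#'   the reporting grid), `nuis` (fitted nuisance models), `h`,
#'   `estimator`, `converged`, `call`. Methods: `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`, and
#'   [as.data.frame.gplm_theta()] for curve export.
#' @examples
#' sim <- simulate_gplm_data(sim_config(n = 400, seed = 7))
#' df <- data.frame(y = sim$data$y, x = sim$data$x[, 1],
#'                  z = sim$data$z, u = sim$data$u[, 1])
#' fit <- gplm(y ~ x, nonpar = ~ z, data = df, aux = ~ u,
#'             bandwidth = 0.15)
#' summary(fit)
#' @export
gplm <- function(formula, nonpar, data, aux = NULL,
                 estimator = c("aipw", "ipw", "naive"),
                 pi_formula = NULL, pi_known = NULL,
                 delta_formula = NULL, delta_fixed = NULL,
                 delta_weights = NULL,
                 link = "identity", kernel = "epanechnikov",
                 bandwidth = "ebbs",
                 variance = c("constant", "loglinear"),
                 control = gplm_control()) {
  estimator <- match.arg(estimator)
  variance <- match.arg(variance)
  cl <- match.call()
  if (!inherits(formula, "formula") || length(formula) != 3L)
    stop("'formula' must be two-sided, e.g. y ~ x1 + x2")
  if (!inherits(nonpar, "formula") || length(nonpar) != 2L)
    stop("'nonpar' must be one-sided, e.g. ~ z")

  y <- eval(formula[[2]], data, environment(formula))
  xt <- stats::terms(formula, data = data)
  xmat <- stats::model.matrix(
    stats::update(formula, NULL ~ . - 1), data)
  zvars <- all.vars(nonpar)
  if (length(zvars) != 1L)
    stop("'nonpar' must name exactly one variable")
  z <- eval(nonpar[[2]], data, environment(nonpar))
  umat <- if (is.null(aux)) NULL else
    stats::model.matrix(stats::update(aux, ~ . - 1), data)
  d <- observed_data(y = y, x = xmat, z = z, u = umat)

  default_nuis <- function() {
    rhs <- c(colnames(xmat), zvars, colnames(umat))
    stats::reformulate(rhs)
  }
  pi_design <- NULL
  if (estimator != "naive" && is.null(pi_known)) {
    pf <- if (is.null(pi_formula)) default_nuis() else pi_formula
    pi_design <- stats::model.matrix(pf, data)
  }
  delta_design <- NULL
  if (estimator == "aipw" && is.null(delta_fixed)) {
    df_ <- if (is.null(delta_formula)) default_nuis() else delta_formula
    delta_design <- stats::model.matrix(df_, data)
  }

  lk <- resolve_link(link)
  kn <- resolve_kernel(kernel)
  h <- bandwidth
  ebbs <- NULL
  if (identical(bandwidth, "ebbs")) {
    pi0 <- if (estimator == "naive") rep(1, d$n) else if (!is.null(pi_known))
      rep_len(pi_known, d$n) else
      fit_missingness(d, design = pi_design,
                      pi_floor = control$pi_floor)$pi
    init <- initial_fit(d, pi0, h = 0.15 * diff(range(d$z)), lk, kn, control)
    nuis0 <- gplm_nuisance(pi = pi0, v = 1, n = d$n)
    ebbs <- ebbs_select(d, nuis0, init$beta_check, "ipw", lk, kn, control)
    h <- ebbs$h_global
  }
  if (!is.numeric(h) || h <= 0)
    stop("'bandwidth' must be a positive number or \"ebbs\"")

  fit <- gplm_fit(d, estimator = estimator, h = h,
                  pi_design = pi_design, pi_known = pi_known,
                  delta_design = delta_design, delta_fixed = delta_fixed,
                  delta_weights = delta_weights,
                  link = lk, kernel = kn, variance = variance,
                  control = control)
  names(fit$beta) <- colnames(xmat)
  if (!is.null(fit$se)) names(fit$se) <- colnames(xmat)
  fit$call <- cl
  fit$formula <- formula
  fit$nonpar <- nonpar
  fit$ebbs <- ebbs
  fit
}

#' @export
print.gplm <- function(x, digits = 4, ...) {
  cat("Generalized partially linear model (",
      toupper(x$estimator), " kernel-profile fit)\n", sep = "")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("link = %s, kernel = %s, h = %.4g, n = %d (%.1f%% missing)\n",
              x$link$name, x$kernel$name, x$h, x$data$n,
              100 * mean(x$data$r == 0)))
  cat("Coefficients:\n")
  print(signif(x$beta, digits))
  if (!x$converged) cat("WARNING: outer iteration did not converge\n")
  invisible(x)
}

#' @export
summary.gplm <- function(object, ...) {
  est <- object$beta
  se <- object$se
  zval <- est / se
  pval <- 2 * stats::pnorm(-abs(zval))
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `z value` = zval, `Pr(>|z|)` = pval)
  structure(list(coefficients = tab, estimator = object$estimator,
                 link = object$link$name, h = object$h,
                 n = object$data$n,
                 missing_frac = mean(object$data$r == 0),
                 n_truncated = object$nuis$miss$n_truncated,
                 n_outer = object$n_outer, converged = object$converged,
                 call = object$call),
            class = "summary.gplm")
}

#' @export
print.summary.gplm <- function(x, ...) {
  cat("Generalized partially linear model with missing outcomes\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("estimator = %s, link = %s, bandwidth = %.4g\n",
              toupper(x$estimator), x$link, x$h))
  cat(sprintf("n = %d, missing outcomes = %.1f%%", x$n,
              100 * x$missing_frac))
  if (!is.null(x$n_truncated) && x$n_truncated > 0)
    cat(sprintf(", truncated pi-hat: %d", x$n_truncated))
  cat("\n\nCoefficients (sandwich standard errors):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!x$converged) cat("\nWARNING: outer iteration did not converge\n")
  invisible(x)
}

#' @export
coef.gplm <- function(object, ...) object$beta

#' @export
vcov.gplm <- function(object, ...) {
  v <- object$vcov
  dimnames(v) <- list(names(object$beta), names(object$beta))
  v
}

# theta-hat at arbitrary z by interpolation of the fitted curve (the curve
# is evaluated at every observed z plus the reporting grid, so
# interpolation error is negligible at interior points).
theta_at <- function(object, z) {
  stats::approx(object$theta$z_eval, object$theta$alpha0, xout = z,
                rule = 2)$y
}

#' @export
predict.gplm <- function(object, newdata = NULL,
                         type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    lp <- as.numeric(object$data$x %*% object$beta) +
      theta_at(object, object$data$z)
  } else {
    xf <- stats::update(object$formula, NULL ~ . - 1)
    xmat <- stats::model.matrix(xf, newdata)
    z <- eval(object$nonpar[[2]], newdata, environment(object$nonpar))
    lp <- as.numeric(xmat %*% object$beta) + theta_at(object, z)
  }
  if (type == "link") lp else object$link$mu(lp)
}

#' @export
fitted.gplm <- function(object, ...) predict(object)

#' @export
residuals.gplm <- function(object, type = c("response", "working"), ...) {
  type <- match.arg(type)
  mu <- predict(object, type = "response")
  if (type == "response") return(object$data$y - mu)
  y0 <- ifelse(is.na(object$data$y), 0, object$data$y)
  w_r <- object$data$r / object$nuis$pi
  switch(object$estimator,
    aipw = w_r * (y0 - mu) - (w_r - 1) * (object$nuis$delta - mu),
    ipw = w_r * (y0 - mu),
    naive = object$data$r * (y0 - mu))
}

#' @export
plot.gplm <- function(x, level = 0.95, ...) {
  zg <- x$z_grid
  gi <- match(zg, x$theta$z_eval)
  th <- x$theta$alpha0[gi]
  se <- sqrt(x$theta_var_grid)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  graphics::plot(zg, th, type = "l", lwd = 2,
                 ylim = range(th - zq * se, th + zq * se),
                 xlab = "z", ylab = expression(hat(theta)(z)), ...)
  graphics::lines(zg, th - zq * se, lty = 2)
  graphics::lines(zg, th + zq * se, lty = 2)
  graphics::rug(x$data$z, quiet = TRUE)
  invisible(x)
}

#' Export a fitted curve as a data frame
#'
#' @param x a `"gplm_theta"` curve object (e.g. `fit$theta`).
#' @param ... unused.
#' @return a data frame with columns `z`, `theta`, `slope` and the phi
#'   derivative columns.
#' @export
as.data.frame.gplm_theta <- function(x, ...) {
  out <- data.frame(z = x$z_eval, theta = x$alpha0, slope = x$alpha1)
  if (!is.null(x$phi)) {
    phi <- as.matrix(x$phi)
    colnames(phi) <- paste0("phi_", seq_len(ncol(phi)))
    out <- cbind(out, phi)
  }
  out
}
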