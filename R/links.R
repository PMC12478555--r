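#' Link functions for generalized partially linear models
#'
#' Constructs a link object holding the inverse link \eqn{\mu}, its first two
#' derivatives, and overflow protection. The model is
#' \eqn{E(Y|X,Z) = \mu(X^T\beta + \theta(Z))} with a known strictly monotone
#' \eqn{\mu}. Three links are supported: `"identity"` (\eqn{\mu(u)=u}),
#' `"logit"` (\eqn{\mu(u) = 1/(1+e^{-u})}) and `"log"` (\eqn{\mu(u)=e^u}).
#'
#' For the logit and log links the linear predictor is clamped to
#' `[-clamp, clamp]` before exponentiation to avoid overflow; the number of
#' clamped evaluations is accumulated in the object's `clamp_count`
#' environment field.
#'
#' @param name one of `"identity"`, `"logit"`, `"log"`.
#' @param clamp positive magnitude bound on the linear predictor for the
#'   logit and log links (default 30). Ignored for the identity link.
#' @return an object of class `"gplm_link"` with fields `name`, `mu`, `mu1`
#'   (first derivative), `mu2` (second derivative) and `clamp`.
#' @examples
#' lk <- make_link("logit")
#' lk$mu(0)          # 0.5
#' lk$mu1(0)         # 0.25
#' @export
make_link <- function(name = c("identity", "logit", "log"), clamp = 30) {
  name <- match.arg(name)
  stopifnot(is.numeric(clamp), clamp > 0)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  clip <- function(eta) {
    out <- abs(eta) > clamp
    if (any(out)) {
      counter$n <- counter$n + sum(out)
      eta <- pmin(pmax(eta, -clamp), clamp)
    }
    eta
  }
  obj <- switch(name,
    identity = list(
      mu  = function(eta) eta,
      mu1 = function(eta) rep(1, length(eta)),
      mu2 = function(eta) rep(0, length(eta))
    ),
    logit = list(
      mu  = function(eta) stats::plogis(clip(eta)),
      mu1 = function(eta) { p <- stats::plogis(clip(eta)); p * (1 - p) },
      mu2 = function(eta) { p <- stats::plogis(clip(eta)); p * (1 - p) * (1 - 2 * p) }
    ),
    log = list(
      mu  = function(eta) exp(clip(eta)),
      mu1 = function(eta) exp(clip(eta)),
      mu2 = function(eta) exp(clip(eta))
    )
  )
  structure(c(list(name = name, clamp = clamp, clamp_count = counter), obj),
            class = "gplm_link")
}

#' Kernel functions for local-linear smoothing
#'
#' Returns a symmetric mean-zero density \eqn{K} together with the constants
#' \eqn{c_0(K^2) = \int K^2(s)\,ds} and \eqn{c_2(K) = \int s^2 K(s)\,ds} that
#' enter the asymptotic bias and variance of the local-linear estimator.
#' The Epanechnikov kernel \eqn{K(s) = 0.75(1-s^2)_+} is the default
#' throughout the package: its compact support keeps local solves cheap.
#'
#' @param name `"epanechnikov"` or `"gaussian"`.
#' @return an object of class `"gplm_kernel"` with fields `name`, `k` (the
#'   kernel function), `c0`, `c2` and `support` (half-width of the support,
#'   `Inf` for the Gaussian).
#' @examples
#' ker <- make_kernel()
#' ker$k(0)    # 0.75
#' ker$c0      # 3/5
#' @export
make_kernel <- function(name = c("epanechnikov", "gaussian")) {
  name <- match.arg(name)
  obj <- switch(name,
    epanechnikov = list(
      k = function(s) 0.75 * pmax(1 - s^2, 0),
      c0 = 3 / 5, c2 = 1 / 5, support = 1
    ),
    gaussian = list(
      k = function(s) stats::dnorm(s),
      c0 = 1 / (2 * sqrt(pi)), c2 = 1, support = Inf
    )
  )
  structure(c(list(name = name), obj), class = "gplm_kernel")
}

#' Kernel weights at an evaluation point
#'
#' Computes \eqn{K_h(Z_i - z_0) = h^{-1} K((Z_i - z_0)/h)} for all
#' observations. Compact-support kernels give exact zeros outside
#' \eqn{|Z_i - z_0| \le h}.
#'
#' @param z_obs numeric vector of observed smoothing-covariate values.
#' @param z0 scalar evaluation point.
#' @param h positive bandwidth.
#' @param kernel a [make_kernel()] object (default Epanechnikov).
#' @return nonnegative numeric vector of length `length(z_obs)`.
#' @export
kernel_weights <- function(z_obs, z0, h, kernel = make_kernel()) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("bandwidth 'h' must be a positive number")
  kernel$k((z_obs - z0) / h) / h
}

#' Linear predictor of the partially linear model
#'
#' Returns \eqn{x^T\beta + \theta(z)} for a single design row; no link is
#' applied. Mostly useful for building oracles and tests; vectorized model
#' evaluation happens internally.
#'
#' @param x_row numeric vector of primary covariates (length p).
#' @param beta numeric coefficient vector (length p).
#' @param theta_at_z scalar value of the smooth component at the unit's z.
#' @return scalar linear predictor.
#' @export
eval_linear_predictor <- function(x_row, beta, theta_at_z) {
  if (length(x_row) != length(beta))
    stop("length of 'x_row' (", length(x_row), ") does not match 'beta' (",
         length(beta), ")")
  stopifnot(length(theta_at_z) == 1L)
  sum(x_row * beta) + theta_at_z
}
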