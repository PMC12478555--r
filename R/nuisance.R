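#' Fit the parametric missingness (selection-probability) model
#'
#' Estimates Pr(R = 1 | X, Z, U) = expit(w' tau) by maximum likelihood on a
#' user-supplied design matrix `w` (logistic regression via IRLS), or accepts
#' externally known selection probabilities as in a designed two-stage study.
#' The per-unit score and the empirical information are retained because the
#' sandwich variance of the profile estimator must correct for the estimation
#' of tau; when the probabilities are known the correction term is exactly
#' zero and the score pieces are flagged degenerate.
#'
#' Fitted probabilities below `pi_floor` are truncated (with a warning and a
#' recorded count): very small selection probabilities produce inverse
#' weights that let a few observations dominate the fit.
#'
#' @param data a [observed_data()] object.
#' @param design numeric matrix (n x k) of regressors for the logistic
#'   model, including the intercept column if wanted. Ignored when `known`
#'   is supplied.
#' @param known optional vector (length n, or scalar) of known selection
#'   probabilities in (0, 1].
#' @param pi_floor truncation level for small fitted probabilities
#'   (default 0.01); set to 0 to disable.
#' @return an object of class `"gplm_missingness"`: list with `tau`, `pi`
#'   (length n), `score` (n x k per-unit score of tau, zero matrix when
#'   known), `dscore` (k x k empirical mean derivative of the score),
#'   `design`, `known` (logical), `n_truncated`.
#' @export
fit_missingness <- function(data, design = NULL, known = NULL,
                            pi_floor = 0.01) {
  stopifnot(inherits(data, "gplm_data"))
  n <- data$n
  if (!is.null(known)) {
    pi <- rep_len(as.numeric(known), n)
    if (any(!is.finite(pi)) || any(pi <= 0) || any(pi > 1))
      stop("known selection probabilities must lie in (0, 1]")
    if (any(data$r == 1L & pi == 0))
      stop("observed unit with zero selection probability")
    return(structure(list(tau = NULL, pi = pi,
                          score = matrix(0, n, 0), dscore = NULL,
                          design = NULL, known = TRUE, n_truncated = 0L,
                          pi_floor = pi_floor),
                     class = "gplm_missingness"))
  }
  if (is.null(design)) stop("one of 'design' or 'known' must be supplied")
  w <- as.matrix(design)
  if (nrow(w) != n) stop("design must have n rows")
  r <- data$r
  if (all(r == 1L) || all(r == 0L))
    stop("non-overlap: response indicator is constant (all R = ",
         r[1], "); the missingness MLE does not exist")
  qrw <- qr(w)
  if (qrw$rank < ncol(w)) {
    drop_cols <- setdiff(seq_len(ncol(w)), qrw$pivot[seq_len(qrw$rank)])
    nm <- colnames(w)
    if (is.null(nm)) nm <- paste0("col", seq_len(ncol(w)))
    stop("singular missingness design; offending columns: ",
         paste(nm[drop_cols], collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(w, r, family = stats::binomial(), intercept = FALSE))
  if (!fit$converged)
    stop("logistic missingness model did not converge (possible separation)")
  tau <- fit$coefficients
  pi <- as.numeric(fit$fitted.values)
  eps <- 1e-10
  if (all(pi[r == 0L] < eps) || all(pi[r == 1L] > 1 - eps))
    stop("complete separation in the missingness model")
  n_trunc <- sum(pi < pi_floor)
  if (n_trunc > 0L) {
    warning(sprintf("%d fitted selection probabilities below %.3g truncated",
                    n_trunc, pi_floor))
    pi <- pmax(pi, pi_floor)
  }
  score <- w * (r - pi)                      # per-unit d loglik / d tau
  dscore <- -crossprod(w, w * (pi * (1 - pi))) / n
  structure(list(tau = tau, pi = pi, score = score, dscore = dscore,
                 design = w, known = FALSE, n_truncated = n_trunc,
                 pi_floor = pi_floor),
            class = "gplm_missingness")
}

#' Fit the parametric outcome (augmentation) model
#'
#' Least-squares fit of the working model E(Y | X, Z, U) = d' eta on the
#' complete cases (R = 1), optionally weighted. Under missing at random,
#' E(Y | X, Z, U, R = 1) = E(Y | X, Z, U), so the unweighted complete-case
#' fit is consistent when the model is correct. The fitted mean `delta` is
#' evaluated for every unit, including those with missing outcomes; the
#' per-unit estimating function and its mean derivative feed the sandwich
#' variance.
#'
#' Alternatively a fixed augmentation function can be imposed by supplying
#' its per-unit values through `fixed`: no coefficients are estimated and
#' the eta-correction of the sandwich is dropped.
#'
#' @param data a [observed_data()] object.
#' @param design numeric matrix (n x d) of regressors, evaluated for all
#'   units.
#' @param weights optional positive weights (length n), e.g. `1 / pi_hat`
#'   for an inverse-probability-weighted fit; only complete-case entries are
#'   used.
#' @param fixed optional numeric vector (length n) of fixed augmentation
#'   values delta(X, Z, U); overrides `design`.
#' @return an object of class `"gplm_outcome"`: list with `eta`, `delta`
#'   (length n), `score` (n x d), `dscore` (d x d), `design`, `sigma2`
#'   (complete-case mean squared residual), `known` (logical, TRUE for
#'   fixed delta).
#' @export
fit_outcome_model <- function(data, design = NULL, weights = NULL,
                              fixed = NULL) {
  stopifnot(inherits(data, "gplm_data"))
  n <- data$n
  if (!is.null(fixed)) {
    delta <- rep_len(as.numeric(fixed), n)
    if (any(!is.finite(delta))) stop("fixed delta values must be finite")
    return(structure(list(eta = NULL, delta = delta,
                          score = matrix(0, n, 0), dscore = NULL,
                          design = NULL, sigma2 = NA_real_, known = TRUE),
                     class = "gplm_outcome"))
  }
  if (is.null(design)) stop("one of 'design' or 'fixed' must be supplied")
  d <- as.matrix(design)
  if (nrow(d) != n) stop("design must have n rows")
  cc <- data$r == 1L
  if (sum(cc) < ncol(d))
    stop("fewer complete cases (", sum(cc), ") than outcome-model ",
         "parameters (", ncol(d), ")")
  w <- if (is.null(weights)) rep(1, n) else rep_len(as.numeric(weights), n)
  if (any(w[cc] <= 0)) stop("weights must be positive on complete cases")
  fit <- stats::lm.wfit(d[cc, , drop = FALSE], data$y[cc], w[cc])
  if (fit$rank < ncol(d)) {
    nm <- colnames(d)
    if (is.null(nm)) nm <- paste0("col", seq_len(ncol(d)))
    bad <- nm[is.na(fit$coefficients)]
    stop("rank-deficient outcome design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  eta <- fit$coefficients
  delta <- as.numeric(d %*% eta)
  resid_all <- ifelse(cc, ifelse(is.na(data$y), 0, data$y) - delta, 0)
  score <- d * (w * resid_all)               # l_i; zero rows where R = 0
  dscore <- -crossprod(d[cc, , drop = FALSE],
                       d[cc, , drop = FALSE] * w[cc]) / n
  sigma2 <- sum(resid_all[cc]^2) / sum(cc)
  structure(list(eta = eta, delta = delta, score = score, dscore = dscore,
                 design = d, sigma2 = sigma2, known = FALSE),
            class = "gplm_outcome")
}

#' Fit the working variance model
#'
#' Estimates the working model V(X, Z; zeta) for the conditional variance of
#' the weighted residual. Given a current fit Q_i = mu(x_i' beta + theta(z_i)),
#' the squared AIPW residuals
#' \deqn{S_i = \{R_i \hat\pi_i^{-1}(Y_i - Q_i) -
#'   (R_i\hat\pi_i^{-1} - 1)(\hat\delta_i - Q_i)\}^2}
#' are regressed on the variance model by (nonlinear) least squares; for the
#' IPW branch the squared residuals are
#' \eqn{\tilde S_i = R_i \hat\pi_i^{-1} (Y_i - Q_i)^2}. The working variance
#' only affects efficiency weighting, not consistency, so a misspecified
#' family is harmless asymptotically.
#'
#' Two families are shipped: `"constant"` (V = zeta, closed form: the sample
#' mean of S) and `"loglinear"` (V = exp(zeta0 + zeta1 * lp) in the linear
#' predictor lp, fitted by least squares).
#'
#' @param data a [observed_data()] object.
#' @param pi vector of selection probabilities (length n).
#' @param delta vector of augmentation values (length n); may be `NULL` for
#'   the IPW branch.
#' @param q vector of current fitted means Q_i (length n).
#' @param family `"constant"` or `"loglinear"`.
#' @param ipw logical: use the IPW residual recipe instead of the AIPW one.
#' @param lp linear-predictor values used by the log-linear family
#'   (defaults to `q`, exact for the identity link).
#' @return an object of class `"gplm_variance"`: list with `zeta`, `family`,
#'   and `v_of(lp)`, a positive variance function of the linear predictor.
#' @export
fit_working_variance <- function(data, pi, delta = NULL, q,
                                 family = c("constant", "loglinear"),
                                 ipw = FALSE, lp = q) {
  stopifnot(inherits(data, "gplm_data"))
  family <- match.arg(family)
  r <- data$r
  y0 <- ifelse(is.na(data$y), 0, data$y)
  if (ipw) {
    s <- (r / pi) * (y0 - q)^2
  } else {
    if (is.null(delta)) stop("AIPW residuals require 'delta'")
    s <- ((r / pi) * (y0 - q) - (r / pi - 1) * (delta - q))^2
  }
  if (family == "constant") {
    zeta <- mean(s)
    if (zeta <= 0) stop("degenerate working variance: mean squared residual ",
                        "is not positive")
    v_of <- local({ z <- zeta; function(lp) rep(z, length(lp)) })
  } else {
    obj <- function(par) sum((s - exp(par[1] + par[2] * lp))^2)
    opt <- stats::optim(c(log(mean(s)), 0), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (opt$convergence != 0)
      stop("working-variance least squares did not converge (code ",
           opt$convergence, "; value ", format(opt$value), ")")
    zeta <- opt$par
    v_of <- local({ z <- zeta; function(lp) exp(z[1] + z[2] * lp) })
  }
  structure(list(zeta = zeta, family = family, v_of = v_of, s = s),
            class = "gplm_variance")
}
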