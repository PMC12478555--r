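#' Observed data for a partially linear model with missing outcomes
#'
#' Bundles one study's data: outcome `y` (possibly missing), response
#' indicator `r` (1 = observed), primary covariates `x`, scalar smoothing
#' covariate `z`, and auxiliary covariates `u`. Auxiliary covariates are not
#' part of the target regression E(Y|X,Z) but carry the missing-at-random
#' assumption: Pr(R=1 | X, Z, U, Y) = Pr(R=1 | X, Z, U).
#'
#' @param y numeric outcome vector; `NA` where missing.
#' @param x numeric matrix (n x p) or vector of primary covariates.
#' @param z numeric vector, the scalar covariate entering the model through
#'   the unknown smooth function theta.
#' @param u optional numeric matrix (n x q) or vector of auxiliary
#'   covariates.
#' @param r optional 0/1 response indicator; defaults to `!is.na(y)`. An
#'   explicit `r` must be consistent with the missingness of `y`.
#' @return an object of class `"gplm_data"`: a list with elements `y`, `r`,
#'   `x`, `z`, `u`, `n`, `p`.
#' @examples
#' d <- observed_data(y = c(1, 2, NA, 4, 5, NA, 7, 8),
#'                    x = rnorm(8), z = runif(8), u = rnorm(8))
#' d$r
#' @export
observed_data <- function(y, x, z, u = NULL, r = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  z <- as.numeric(z)
  if (is.null(u)) {
    u <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    u <- as.matrix(u)
    storage.mode(u) <- "double"
    if (ncol(u) > 0 && is.null(colnames(u)))
      colnames(u) <- paste0("u", seq_len(ncol(u)))
  }
  if (nrow(x) != n || length(z) != n || nrow(u) != n)
    stop("y, x, z, u must have a common number of rows")
  if (is.null(r)) {
    r <- as.integer(!is.na(y))
  } else {
    r <- as.integer(r)
    if (length(r) != n || !all(r %in% c(0L, 1L)))
      stop("'r' must be a 0/1 vector of length n")
    bad <- which(r == 1L & is.na(y))
    if (length(bad))
      stop("rows with r = 1 but missing y: ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(y[r == 1L])))
    stop("y must be finite wherever r = 1")
  if (any(is.na(z)) || any(!is.finite(x)) || (ncol(u) > 0 && any(!is.finite(u))))
    stop("x, z, u must be complete and finite")
  if (n < ncol(x) + 2L)
    stop("need at least p + 2 observations")
  if (length(unique(z)) < 2L)
    stop("z must take at least 2 distinct values")
  y[r == 0L] <- NA_real_
  structure(list(y = y, r = r, x = x, z = z, u = u, n = n, p = ncol(x)),
            class = "gplm_data")
}

#' @export
print.gplm_data <- function(x, ...) {
  cat("Partially linear model data: n =", x$n,
      " p =", x$p, " q =", ncol(x$u), "\n")
  cat(sprintf("missing outcomes: %d (%.1f%%)\n",
              sum(x$r == 0L), 100 * mean(x$r == 0L)))
  invisible(x)
}

#' Read a delimited dataset into a gplm_data object
#'
#' Reads a header-ed delimited text file (CSV by default, `NA` or empty cells
#' for missing outcomes) and maps named columns onto the model roles. If no
#' response-indicator column is named, `r` is derived as the indicator of a
#' nonmissing outcome.
#'
#' @param path file path.
#' @param y,z single column names for the outcome and smoothing covariate.
#' @param x,u character vectors of column names for primary and auxiliary
#'   covariates (`u` may be empty).
#' @param r optional column name of an explicit 0/1 response indicator.
#' @param sep field separator (default comma).
#' @return a [observed_data()] object.
#' @export
read_gplm_data <- function(path, y, x, z, u = character(0), r = NULL,
                           sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", ""), check.names = FALSE)
  need <- c(y, x, z, u, r)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  for (cc in need) {
    if (!is.numeric(df[[cc]]))
      stop("column '", cc, "' is not numeric")
  }
  if (all(is.na(df[[y]])))
    stop("all outcome values are missing")
  observed_data(y = df[[y]],
                x = as.matrix(df[x]),
                z = df[[z]],
                u = if (length(u)) as.matrix(df[u]) else NULL,
                r = if (is.null(r)) NULL else df[[r]])
}

#' Write a gplm_data object to delimited text
#'
#' Inverse of [read_gplm_data()]: writes columns `y`, `r`, the `x` columns,
#' `z` and the `u` columns, with `NA` for missing outcomes.
#'
#' @param data a [observed_data()] object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_gplm_data <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "gplm_data"))
  df <- data.frame(y = data$y, r = data$r, data$x, z = data$z,
                   check.names = FALSE)
  if (ncol(data$u) > 0) df <- cbind(df, data$u)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
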