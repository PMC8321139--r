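#' Residual spatial correlation specifications
#'
#' Five correlation families are available for the within-eye residual
#' process. With `d` the Euclidean centroid distance (mm) and `delta` the
#' integer lag under the grid's sector ordering:
#'
#' * `ar_lag`:       `gamma^delta`, `gamma` in (0, 1);
#' * `gaussian`:     `exp(-gamma * d^2)`, `gamma > 0`;
#' * `exponential`:  `exp(-gamma * d)`, `gamma > 0`;
#' * `spherical`:    `1 - (3*gamma*d - gamma^3*d^3)/2` for `d < 1/gamma`,
#'                   clamped to 0 beyond that range, `gamma > 0`;
#' * `independence`: identity correlation (no parameter).
#'
#' `gamma` is a rate: larger values mean faster decay. Use
#' [rate_to_range()] / [range_to_rate()] to convert to the range
#' parameterisation `exp(-d / range)` used elsewhere (e.g. nlme's
#' `corExp`).
#'
#' @param family One of `"exponential"`, `"gaussian"`, `"spherical"`,
#'   `"ar_lag"`, `"independence"`.
#' @param gamma Kernel parameter; `NA` means "to be estimated" in a model
#'   specification. Ignored by `independence`.
#' @return An object of class `corr_spec`.
#' @examples
#' kernel_value(corr_spec("exponential", 0.1), 10)  # exp(-1)
#' @export
corr_spec <- function(family = c("exponential", "gaussian", "spherical",
                                 "ar_lag", "independence"),
                      gamma = NA_real_) {
  family <- match.arg(family)
  if (family == "independence") gamma <- NA_real_
  if (!is.na(gamma)) .check_gamma(family, gamma)
  structure(list(family = family, gamma = as.numeric(gamma)),
            class = "corr_spec")
}

.check_gamma <- function(family, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma))
    stop("'gamma' must be a finite numeric scalar")
  if (family == "ar_lag") {
    if (gamma <= 0 || gamma >= 1) stop("ar_lag requires gamma in (0, 1)")
  } else if (family != "independence") {
    if (gamma <= 0) stop(family, " requires gamma > 0")
  }
  invisible(TRUE)
}

#' @export
print.corr_spec <- function(x, ...) {
  cat("Correlation family:", x$family,
      if (x$family != "independence")
        paste0("(gamma = ", ifelse(is.na(x$gamma), "to be estimated",
                                   format(x$gamma, digits = 5)), ")"),
      "\n")
  invisible(x)
}

#' Evaluate a correlation kernel
#'
#' @param spec A [corr_spec()] with a concrete `gamma`.
#' @param d Nonnegative distances in mm (spatial families) or nonnegative
#'   integer lags (`ar_lag`). Vectorised.
#' @return Correlations in `[0, 1]`; 1 at `d = 0`, non-increasing in `d`.
#' @export
kernel_value <- function(spec, d) {
  stopifnot(inherits(spec, "corr_spec"))
  if (any(d < 0)) stop("distances/lags must be nonnegative")
  fam <- spec$family
  if (fam == "independence") return(as.numeric(d == 0))
  g <- spec$gamma
  .check_gamma(fam, g)
  switch(fam,
    ar_lag = {
      if (any(d != round(d))) stop("ar_lag requires integer lags")
      g^d
    },
    gaussian = exp(-g * d^2),
    exponential = exp(-g * d),
    spherical = {
      v <- 1 - 0.5 * (3 * g * d - g^3 * d^3)
      # beyond the support 1/gamma the polynomial goes negative: clamp
      v[d >= 1 / g] <- 0
      v
    })
}

#' Build the residual correlation matrix over a sector grid
#'
#' Applies [kernel_value()] to the grid's distance matrix (lag matrix for
#' `ar_lag`). The result is checked for positive semi-definiteness: a
#' minimum eigenvalue below `-1e-8` is an error; slight indefiniteness in
#' `(-1e-8, 1e-10)` (possible for spherical/AR kernels on irregular
#' lattices) is repaired by clipping eigenvalues at `1e-10` and restoring
#' a unit diagonal.
#'
#' @param spec A [corr_spec()] with concrete `gamma` (except
#'   `independence`).
#' @param grid A [sector_grid].
#' @return Symmetric correlation matrix with unit diagonal, dimnames from
#'   `grid$sector_ids`.
#' @export
correlation_matrix <- function(spec, grid) {
  stopifnot(inherits(spec, "corr_spec"), inherits(grid, "sector_grid"))
  n <- length(grid$sector_ids)
  if (spec$family == "independence") {
    C <- diag(n)
    dimnames(C) <- list(grid$sector_ids, grid$sector_ids)
    return(C)
  }
  D <- if (spec$family == "ar_lag") lag_matrix(grid) else grid$distance_matrix
  C <- kernel_value(spec, D)
  dim(C) <- dim(D)
  diag(C) <- 1
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < -1e-8)
    stop("correlation matrix is indefinite (min eigenvalue ",
         format(min(lam)), "); choose a different family or gamma")
  if (min(lam) < 1e-10) {
    lam <- pmax(lam, 1e-10)
    C <- ev$vectors %*% (lam * t(ev$vectors))
    s <- sqrt(diag(C))
    C <- C / tcrossprod(s)
  }
  dimnames(C) <- list(grid$sector_ids, grid$sector_ids)
  C
}

#' Convert between rate and range decay parameterisations
#'
#' The exponential kernel is written here as `exp(-gamma * d)` with a rate
#' `gamma`; the geostatistical convention (and nlme's `corExp`) writes
#' `exp(-d / range)`. The two are reciprocal.
#'
#' @param gamma Rate parameter (> 0).
#' @param range Range parameter (> 0).
#' @return The converted parameter.
#' @export
rate_to_range <- function(gamma) {
  stopifnot(is.numeric(gamma), all(gamma > 0))
  1 / gamma
}

#' @rdname rate_to_range
#' @export
range_to_rate <- function(range) {
  stopifnot(is.numeric(range), all(range > 0))
  1 / range
}
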