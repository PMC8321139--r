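# Likelihood machinery.
#
# All quadratic forms run through one pass over the compiled patterns:
# each pattern's block V is Cholesky-factorised once, the stacked Y and X
# are whitened by triangular solves, and X'V^-1 X, X'V^-1 y, y'V^-1 y and
# log|V| are accumulated. No covariance matrix is ever inverted.

# internal: accumulate GLS pieces for covariance blocks V (any scale).
# Returns NULL if any block fails to factorise.
gls_pieces <- function(blocks, Vfun) {
  p <- blocks$p
  logdet <- 0
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  yty <- 0
  for (pat in blocks$patterns) {
    V <- Vfun(pat)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    m_k <- pat$m
    W <- backsolve(R, cbind(pat$Y, pat$Xflat), transpose = TRUE)
    Wy <- W[, seq_len(m_k), drop = FALSE]
    Wx <- W[, -seq_len(m_k), drop = FALSE]
    A <- matrix(aperm(array(Wx, c(pat$n, p, m_k)), c(1, 3, 2)),
                pat$n * m_k, p)
    XtX <- XtX + crossprod(A)
    Xty <- Xty + drop(crossprod(A, as.vector(Wy)))
    yty <- yty + sum(Wy^2)
    logdet <- logdet + 2 * m_k * sum(log(diag(R)))
  }
  list(logdet = logdet, XtX = XtX, Xty = Xty, yty = yty, N = blocks$N)
}

# internal: V builder closure on the unit residual scale
unit_V_fun <- function(blocks, r_b2, r_u2, Cfull, lambda) {
  function(pat) build_block_V(pat, r_b2, r_u2, Cfull, lambda)
}

# internal: pieces at a full variance_components theta (H scale)
full_theta_pieces <- function(blocks, theta, design) {
  Cfull <- resolve_correlation(design$spec$correlation, theta$gamma,
                               design$grid)
  lambda <- resolve_lambda(theta, design$lambda_levels)
  s2 <- theta$sd_resid^2
  pieces <- gls_pieces(blocks,
                       unit_V_fun(blocks, theta$sd_patient^2 / s2,
                                  theta$sd_eye^2 / s2, Cfull, lambda))
  if (is.null(pieces)) stop("covariance block is not positive definite")
  # rescale unit-V pieces to the H = s2 * V scale
  pieces$logdet <- pieces$logdet + pieces$N * log(s2)
  pieces$XtX <- pieces$XtX / s2
  pieces$Xty <- pieces$Xty / s2
  pieces$yty <- pieces$yty / s2
  pieces
}

#' Marginal Gaussian log-likelihood of an SLME model
#'
#' Evaluates the multivariate-normal log-density of the data under fixed
#' effects `beta` and variance components `theta`, summed over the
#' independent per-patient blocks. The additive constant
#' `-(N/2) log(2*pi)` is included, so values are comparable across
#' models fitted by this package. Computation is by Cholesky
#' factorisation (log-determinants from the factor, triangular solves,
#' no explicit inverses).
#'
#' @param beta Fixed-effects vector, aligned with the columns of the
#'   design matrix implied by `spec` (see [build_design()]).
#' @param theta A [variance_components()].
#' @param data Long-format data frame.
#' @param spec An [slme_spec()].
#' @param grid A [sector_grid].
#' @return Log-likelihood (scalar).
#' @export
slme_loglik_ml <- function(beta, theta, data, spec, grid = etdrs_grid()) {
  design <- build_design(data, spec, grid)
  blocks <- compile_blocks(design)
  if (length(beta) != blocks$p)
    stop("'beta' must have length ", blocks$p)
  pieces <- full_theta_pieces(blocks, theta, design)
  quad <- pieces$yty - 2 * sum(beta * pieces$Xty) +
    drop(crossprod(beta, pieces$XtX %*% beta))
  -0.5 * (pieces$N * log(2 * pi) + pieces$logdet + quad)
}

#' Restricted (REML) log-likelihood of an SLME model
#'
#' Evaluates the restricted log-likelihood at variance components
#' `theta`, with the fixed effects profiled out by generalised least
#' squares. The convention used is
#' `lR = -((N - p)/2) log(2*pi) - log|H|/2 - log|X'H^-1 X|/2 -
#' r'H^-1 r / 2` with `r` the GLS residual, which makes
#' `lR = l(beta_hat, theta) - log|X'H^-1 X|/2 + (p/2) log(2*pi)` an
#' exact identity and leaves `lR` invariant under full-rank linear
#' reparametrisations of `X`.
#'
#' @inheritParams slme_loglik_ml
#' @return Restricted log-likelihood (scalar).
#' @export
slme_loglik_reml <- function(theta, data, spec, grid = etdrs_grid()) {
  design <- build_design(data, spec, grid)
  blocks <- compile_blocks(design)
  pieces <- full_theta_pieces(blocks, theta, design)
  p <- blocks$p
  Rx <- chol(pieces$XtX)
  beta <- backsolve(Rx, backsolve(Rx, pieces$Xty, transpose = TRUE))
  rss <- pieces$yty - sum(beta * pieces$Xty)
  -0.5 * ((pieces$N - p) * log(2 * pi) + pieces$logdet +
            2 * sum(log(diag(Rx))) + rss)
}

#' Generalised least squares fixed effects at given variance components
#'
#' Computes `beta_hat = (X'H^-1 X)^-1 X'H^-1 y` and its model-based
#' covariance `(X'H^-1 X)^-1` for fixed variance components.
#'
#' @inheritParams slme_loglik_ml
#' @return List with `beta` (named), `cov_beta`, and `rss`
#'   (the GLS quadratic form `r'H^-1 r`).
#' @export
slme_gls <- function(theta, data, spec, grid = etdrs_grid()) {
  design <- build_design(data, spec, grid)
  blocks <- compile_blocks(design)
  pieces <- full_theta_pieces(blocks, theta, design)
  Rx <- chol(pieces$XtX)
  beta <- drop(backsolve(Rx, backsolve(Rx, pieces$Xty, transpose = TRUE)))
  names(beta) <- colnames(design$X)
  cov_beta <- chol2inv(Rx)
  dimnames(cov_beta) <- list(names(beta), names(beta))
  rss <- pieces$yty - sum(beta * pieces$Xty)
  list(beta = beta, cov_beta = cov_beta, rss = rss)
}
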