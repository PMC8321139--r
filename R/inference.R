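#' Wald tests on fixed effects
#'
#' Tests a single coefficient (z test against `null`) or a set of
#' coefficients jointly equal to zero (chi-square statistic
#' `b' V^-1 b` on `q` degrees of freedom using the model-based
#' covariance, or the corresponding F statistic with a between-within
#' denominator df at the eye level). The "shape effect" of a grouping
#' variable — whether the sector profile's form differs between groups —
#' is the joint test of all group-by-sector interaction coefficients;
#' select them with `pattern` (a regular expression on coefficient
#' names).
#'
#' @param fitted An `slme_fit`.
#' @param coefficients Character vector of coefficient names to test
#'   jointly (or a single name).
#' @param pattern Alternatively, a regular expression matched against
#'   coefficient names.
#' @param null Null value for a single-coefficient test (default 0).
#' @param test `"chisq"` (default) or `"F"` for joint tests.
#' @return An object of class `slme_test`: list with `statistic`, `df`
#'   (`df2` for F), `p_value`, `estimates`, `se`, `kind`.
#' @export
wald_test <- function(fitted, coefficients = NULL, pattern = NULL,
                      null = 0, test = c("chisq", "F")) {
  stopifnot(inherits(fitted, "slme_fit"))
  test <- match.arg(test)
  beta <- fitted$coefficients
  if (is.null(coefficients)) {
    if (is.null(pattern)) stop("give 'coefficients' or 'pattern'")
    coefficients <- grep(pattern, names(beta), value = TRUE)
  }
  if (!length(coefficients)) stop("no coefficients selected")
  miss <- setdiff(coefficients, names(beta))
  if (length(miss))
    stop("unknown coefficient(s): ", paste(miss, collapse = ", "))
  b <- beta[coefficients]
  V <- fitted$vcov[coefficients, coefficients, drop = FALSE]
  se <- sqrt(diag(V))
  q <- length(b)
  if (q == 1) {
    z <- (b - null) / se
    out <- list(statistic = unname(z), df = 1,
                p_value = unname(2 * stats::pnorm(-abs(z))),
                estimates = b, se = se, kind = "wald-z")
  } else {
    Rv <- tryCatch(chol(V), error = function(e)
      stop("singular covariance sub-matrix for the requested set"))
    w <- backsolve(Rv, b, transpose = TRUE)
    W <- sum(w^2)
    if (test == "chisq") {
      out <- list(statistic = W, df = q,
                  p_value = stats::pchisq(W, q, lower.tail = FALSE),
                  estimates = b, se = se, kind = "wald-chisq")
    } else {
      # between-within df at the eye level: number of eyes minus the
      # number of fixed effects (coarse, documented approximation)
      df2 <- max(length(fitted$blups$u), fitted$n_eff / 9) - fitted$p_fixed
      df2 <- max(df2, 1)
      Fst <- W / q
      out <- list(statistic = Fst, df = q, df2 = df2,
                  p_value = stats::pf(Fst, q, df2, lower.tail = FALSE),
                  estimates = b, se = se, kind = "wald-F")
    }
  }
  class(out) <- "slme_test"
  out
}

#' Likelihood-ratio test between nested SLME fits
#'
#' The statistic is `2 * (logLik_full - logLik_reduced)`, clipped at
#' zero, referred to a chi-square distribution with df equal to the
#' difference in parameter counts. Both fits must use the same
#' estimation method; REML comparisons additionally require identical
#' fixed-effects designs (REML likelihoods are not comparable
#' otherwise). When the models differ in variance components the naive
#' chi-square reference is conservative (the null lies on the boundary
#' of the parameter space); the result carries a `boundary_caveat`
#' flag in that case.
#'
#' @param fitted_full,fitted_reduced Nested `slme_fit` objects.
#' @return An `slme_test` with `statistic`, `df`, `p_value`,
#'   `boundary_caveat`.
#' @export
slme_lrt <- function(fitted_full, fitted_reduced) {
  stopifnot(inherits(fitted_full, "slme_fit"),
            inherits(fitted_reduced, "slme_fit"))
  if (fitted_full$method != fitted_reduced$method)
    stop("both fits must use the same estimation method")
  if (fitted_full$method == "REML" &&
      !identical(fitted_full$x_names, fitted_reduced$x_names))
    stop("REML likelihood-ratio tests require identical fixed effects")
  df <- (fitted_full$p_fixed + fitted_full$n_theta) -
    (fitted_reduced$p_fixed + fitted_reduced$n_theta)
  if (df <= 0) stop("'fitted_reduced' must be nested in 'fitted_full'")
  stat <- max(0, 2 * (fitted_full$loglik - fitted_reduced$loglik))
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              boundary_caveat =
                fitted_full$n_theta != fitted_reduced$n_theta,
              kind = "lrt")
  class(out) <- "slme_test"
  out
}

#' @export
print.slme_test <- function(x, ...) {
  cat(x$kind, "test: statistic =", format(x$statistic, digits = 5),
      " df =", x$df,
      if (!is.null(x$df2)) paste0("/", round(x$df2, 1)),
      " p =", format.pval(x$p_value, digits = 4), "\n")
  if (isTRUE(x$boundary_caveat))
    cat("  (variance-component null on the boundary:",
        "the chi-square reference is conservative)\n")
  invisible(x)
}

#' Information criteria of a fitted SLME model
#'
#' `AIC = -2 l + 2 p` with `p` the total number of estimated parameters
#' (fixed effects plus variance parameters). The default BIC is
#' `-2 l + p log(n_eff)` where `n_eff` is the number of observations
#' under ML and `n - p_fixed` under REML. `bic_doubled_penalty = TRUE`
#' uses `-2 l + 2 p log(n_eff)` instead (a doubled penalty some
#' sources print); rankings may then differ from the standard BIC.
#'
#' @param fitted An `slme_fit`.
#' @param bic_doubled_penalty Use the doubled BIC penalty.
#' @return Named vector `c(aic = ..., bic = ...)`.
#' @export
information_criteria <- function(fitted, bic_doubled_penalty = FALSE) {
  stopifnot(inherits(fitted, "slme_fit"))
  p_total <- fitted$p_fixed + fitted$n_theta
  mult <- if (bic_doubled_penalty) 2 else 1
  c(aic = -2 * fitted$loglik + 2 * p_total,
    bic = -2 * fitted$loglik + mult * p_total * log(fitted$n_eff))
}
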