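#' Specify a spatial linear mixed effects model
#'
#' An SLME model couples (i) a fixed-effects mean structure given as a
#' formula over patient-level covariates, eye-level covariates, the
#' `sector` factor and their interactions, (ii) nested random intercepts
#' for patient and/or eye-within-patient, (iii) a residual spatial
#' correlation structure over the sector grid, and (iv) optional
#' heteroscedastic residual weights by a grouping factor.
#'
#' The formula may use the column `sector`, a factor over the grid's
#' sector ids whose baseline level is `reference_sector` (central
#' subfield by default); it is derived from the `sector_id` column.
#'
#' @param fixed A formula, e.g.
#'   `thickness ~ age + group + sector + group:sector`.
#' @param random Character vector: random-intercept levels, a subset of
#'   `c("patient", "eye")` (eye means eye-within-patient). May be empty
#'   (`character(0)`) for a purely marginal model.
#' @param correlation A [corr_spec()]. A `gamma` of `NA` is estimated;
#'   a concrete `gamma` is held fixed.
#' @param weights_by Optional name of a grouping column; the residual
#'   standard deviation is multiplied per cell by a group ratio
#'   `lambda_g`, with the reference group fixed at 1.
#' @param weights_reference Reference level for `weights_by` (defaults to
#'   the factor's first level).
#' @param reference_sector Baseline sector for the `sector` factor.
#' @return An object of class `slme_spec`.
#' @export
slme_spec <- function(fixed,
                      random = c("patient", "eye"),
                      correlation = corr_spec("exponential"),
                      weights_by = NULL,
                      weights_reference = NULL,
                      reference_sector = "CS") {
  stopifnot(inherits(fixed, "formula"), inherits(correlation, "corr_spec"))
  if (length(random) && !all(random %in% c("patient", "eye")))
    stop("'random' must be a subset of c(\"patient\", \"eye\")")
  structure(list(fixed = fixed, random = unique(random),
                 correlation = correlation, weights_by = weights_by,
                 weights_reference = weights_reference,
                 reference_sector = reference_sector),
            class = "slme_spec")
}

#' @export
print.slme_spec <- function(x, ...) {
  cat("SLME model specification\n")
  cat("  Fixed:      ", deparse(x$fixed), "\n")
  cat("  Random:     ", if (length(x$random))
    paste(x$random, collapse = " + ") else "(none)", "\n")
  cat("  Correlation:", x$correlation$family, "\n")
  if (!is.null(x$weights_by))
    cat("  Weights by: ", x$weights_by, "\n")
  invisible(x)
}

#' Variance components of an SLME model
#'
#' Bundles the standard deviations of the nested random intercepts, the
#' residual scale, the spatial kernel parameter and any heteroscedastic
#' group ratios. The marginal covariance of one patient's data is
#' `H = sd_patient^2 J + blockdiag_eyes(sd_eye^2 J_eye +
#' sd_resid^2 Lambda C Lambda)` with `Lambda = diag(lambda_g)` and `C`
#' the kernel correlation over observed sectors.
#'
#' @param sd_patient Between-patient SD (>= 0).
#' @param sd_eye Between-eye-within-patient SD (>= 0).
#' @param sd_resid Residual SD (> 0), micrometres.
#' @param gamma Kernel parameter (may be `NA` for independence).
#' @param weight_ratios Named numeric vector of per-group residual SD
#'   ratios; the reference group must have ratio 1.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(sd_patient = 0, sd_eye = 0, sd_resid = 1,
                                gamma = NA_real_, weight_ratios = NULL) {
  stopifnot(sd_patient >= 0, sd_eye >= 0, sd_resid > 0)
  if (!is.null(weight_ratios)) {
    if (is.null(names(weight_ratios)) || any(weight_ratios <= 0))
      stop("'weight_ratios' must be a named vector of positive ratios")
  }
  structure(list(sd_patient = sd_patient, sd_eye = sd_eye,
                 sd_resid = sd_resid, gamma = as.numeric(gamma),
                 weight_ratios = weight_ratios),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (SD scale):\n")
  cat("  patient:", format(x$sd_patient, digits = 5),
      " eye:", format(x$sd_eye, digits = 5),
      " residual:", format(x$sd_resid, digits = 5), "\n")
  if (!is.na(x$gamma)) cat("  kernel gamma:", format(x$gamma, digits = 5), "\n")
  if (!is.null(x$weight_ratios)) {
    cat("  residual SD ratios:\n")
    print(round(x$weight_ratios, 4))
  }
  invisible(x)
}

#' Optimiser control for [slme_fit()]
#'
#' @param n_starts Number of optimisation starts (first at the
#'   method-of-moments initial value, remainder jittered).
#' @param jitter_sd SD of the Gaussian jitter applied to the transformed
#'   parameters for extra starts.
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum BFGS iterations.
#' @param boundary_tol Transformed parameters with absolute value beyond
#'   this are flagged as boundary estimates.
#' @param grad_tol Threshold on the final numerical gradient norm used by
#'   the honest `converged` flag (scaled by `1 + |objective|`).
#' @return A list of class `slme_control`.
#' @export
slme_control <- function(n_starts = 3, jitter_sd = 0.5, reltol = 1e-10,
                         maxit = 500, boundary_tol = 6, grad_tol = 1e-4) {
  structure(list(n_starts = n_starts, jitter_sd = jitter_sd,
                 reltol = reltol, maxit = maxit,
                 boundary_tol = boundary_tol, grad_tol = grad_tol),
            class = "slme_control")
}
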