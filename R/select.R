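#' Top-down model selection for SLME models
#'
#' Implements the staged selection strategy for mixed models:
#'
#' 1. fit a saturated fixed-effects model with a working independence
#'    residual structure and the richest candidate random structure;
#' 2. choose the random-intercept structure among candidates by REML
#'    AIC (BIC and likelihood-ratio tests are reported alongside);
#' 3. choose the residual correlation family among candidates by REML
#'    AIC/BIC, keeping the chosen random structure;
#' 4. simplify the fixed effects among nested candidates by ML AIC/BIC
#'    (each reduced model is also compared to the saturated one by a
#'    likelihood-ratio test);
#'
#' then refit the winning configuration by REML.
#'
#' @param data Long-format data frame.
#' @param saturated_fixed Formula: the saturated fixed-effects model.
#' @param candidate_random List of character vectors (subsets of
#'   `c("patient", "eye")`), richest first.
#' @param candidate_correlations List of [corr_spec()] objects.
#' @param candidate_fixed Optional list of reduced fixed-effects
#'   formulas to consider in stage 4 (the saturated formula is always
#'   included).
#' @param grid A [sector_grid].
#' @param weights_by,weights_reference Passed to [slme_spec()].
#' @param control An [slme_control()].
#' @return List with `final` (REML `slme_fit` of the selected model),
#'   `selected` (list: random, correlation, fixed) and `trail` (data
#'   frame auditing every candidate fit: stage, candidate, method,
#'   logLik, AIC, BIC, converged, chosen).
#' @export
top_down_select <- function(data, saturated_fixed,
                            candidate_random = list(c("patient", "eye"),
                                                    "patient"),
                            candidate_correlations =
                              list(corr_spec("independence"),
                                   corr_spec("exponential"),
                                   corr_spec("gaussian"),
                                   corr_spec("spherical")),
                            candidate_fixed = list(),
                            grid = etdrs_grid(),
                            weights_by = NULL, weights_reference = NULL,
                            control = slme_control()) {
  trail <- data.frame()
  note <- function(stage, candidate, fit, chosen = FALSE) {
    data.frame(stage = stage, candidate = candidate, method = fit$method,
               logLik = fit$loglik, aic = fit$aic, bic = fit$bic,
               converged = fit$converged, chosen = chosen)
  }
  try_fit <- function(fixed, random, correlation, method) {
    sp <- slme_spec(fixed, random = random, correlation = correlation,
                    weights_by = weights_by,
                    weights_reference = weights_reference)
    tryCatch(slme_fit(data, sp, grid, method = method, control = control),
             error = function(e) NULL)
  }

  # stage 1-2: random structure under working independence, REML
  fits_r <- list()
  for (i in seq_along(candidate_random)) {
    f <- try_fit(saturated_fixed, candidate_random[[i]],
                 corr_spec("independence"), "REML")
    if (!is.null(f)) fits_r[[paste(candidate_random[[i]],
                                   collapse = "+")]] <- f
  }
  if (!length(fits_r)) stop("no random-structure candidate converged")
  best_r <- which.min(vapply(fits_r, `[[`, numeric(1), "aic"))
  for (nm in names(fits_r))
    trail <- rbind(trail, note("random", nm, fits_r[[nm]],
                               nm == names(fits_r)[best_r]))
  random_sel <- candidate_random[[best_r]]

  # stage 3: correlation family, REML
  fits_c <- list()
  for (cs in candidate_correlations) {
    f <- try_fit(saturated_fixed, random_sel, cs, "REML")
    if (!is.null(f)) fits_c[[cs$family]] <- f
  }
  if (!length(fits_c)) stop("no correlation candidate converged")
  best_c <- which.min(vapply(fits_c, `[[`, numeric(1), "aic"))
  for (nm in names(fits_c))
    trail <- rbind(trail, note("correlation", nm, fits_c[[nm]],
                               nm == names(fits_c)[best_c]))
  corr_sel_fam <- names(fits_c)[best_c]
  corr_sel <- candidate_correlations[[
    which(vapply(candidate_correlations, `[[`, character(1), "family") ==
            corr_sel_fam)[1]]]

  # stage 4: fixed-effects reduction, ML
  all_fixed <- c(list(saturated_fixed), candidate_fixed)
  fixed_lab <- vapply(all_fixed, function(f)
    paste(deparse(f), collapse = ""), character(1))
  fits_f <- list()
  for (i in seq_along(all_fixed)) {
    f <- try_fit(all_fixed[[i]], random_sel, corr_sel, "ML")
    if (!is.null(f)) fits_f[[fixed_lab[i]]] <- f
  }
  if (!length(fits_f)) stop("no fixed-effects candidate converged")
  best_f <- which.min(vapply(fits_f, `[[`, numeric(1), "aic"))
  for (nm in names(fits_f))
    trail <- rbind(trail, note("fixed", nm, fits_f[[nm]],
                               nm == names(fits_f)[best_f]))
  fixed_sel <- all_fixed[[match(names(fits_f)[best_f], fixed_lab)]]

  final <- try_fit(fixed_sel, random_sel, corr_sel, "REML")
  if (is.null(final)) stop("final refit failed to converge")
  list(final = final,
       selected = list(random = random_sel, correlation = corr_sel,
                       fixed = fixed_sel),
       trail = trail)
}
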