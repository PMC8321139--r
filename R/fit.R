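# Fitting: profiled ML/REML over transformed variance parameters.
#
# The residual scale sigma_s is profiled out analytically, so the
# optimiser works on the remaining parameters only, each mapped to the
# real line: log of the SD ratios r_b = sd_patient/sd_resid and
# r_u = sd_eye/sd_resid, log gamma (logit for the AR kernel's gamma in
# (0,1)), and log of each non-reference heteroscedastic ratio.

# internal: describe the free transformed parameters for a design
phi_map <- function(design) {
  spec <- design$spec
  nm <- character(0)
  if ("patient" %in% spec$random) nm <- c(nm, "log_rb")
  if ("eye" %in% spec$random) nm <- c(nm, "log_ru")
  est_gamma <- spec$correlation$family != "independence" &&
    is.na(spec$correlation$gamma)
  if (est_gamma) nm <- c(nm, "gamma_t")
  if (!is.null(design$lambda_levels))
    nm <- c(nm, paste0("log_lambda.", design$lambda_levels[-1]))
  list(names = nm, est_gamma = est_gamma,
       ar = spec$correlation$family == "ar_lag",
       n_lambda = if (is.null(design$lambda_levels)) 1L
                  else length(design$lambda_levels))
}

# internal: transformed parameter vector -> natural-scale components
phi_unpack <- function(phi, map, spec) {
  names(phi) <- map$names
  r_b2 <- if ("log_rb" %in% map$names) exp(2 * phi[["log_rb"]]) else 0
  r_u2 <- if ("log_ru" %in% map$names) exp(2 * phi[["log_ru"]]) else 0
  gamma <- if (map$est_gamma) {
    if (map$ar) stats::plogis(phi[["gamma_t"]]) else exp(phi[["gamma_t"]])
  } else spec$correlation$gamma
  lambda <- rep(1, map$n_lambda)
  lnm <- grep("^log_lambda\\.", map$names, value = TRUE)
  if (length(lnm)) lambda[-1] <- exp(phi[lnm])
  list(r_b2 = r_b2, r_u2 = r_u2, gamma = gamma, lambda = lambda)
}

# internal: negative profiled objective (REML or ML) on the phi scale
make_objective <- function(blocks, design, map, method) {
  spec <- design$spec
  grid <- design$grid
  N <- blocks$N
  p <- blocks$p
  force(method)
  function(phi) {
    par <- phi_unpack(phi, map, spec)
    Cfull <- tryCatch(
      resolve_correlation(spec$correlation, par$gamma, grid),
      error = function(e) NULL)
    if (is.null(Cfull)) return(1e10)
    pieces <- gls_pieces(blocks, unit_V_fun(blocks, par$r_b2, par$r_u2,
                                            Cfull, par$lambda))
    if (is.null(pieces)) return(1e10)
    Rx <- tryCatch(chol(pieces$XtX), error = function(e) NULL)
    if (is.null(Rx)) return(1e10)
    beta <- backsolve(Rx, backsolve(Rx, pieces$Xty, transpose = TRUE))
    rss <- max(pieces$yty - sum(beta * pieces$Xty), 1e-12)
    val <- if (method == "REML") {
      df <- N - p
      -0.5 * (df * log(2 * pi * rss / df) + pieces$logdet +
                2 * sum(log(diag(Rx))) + df)
    } else {
      -0.5 * (N * log(2 * pi * rss / N) + pieces$logdet + N)
    }
    if (!is.finite(val)) return(1e10)
    -val
  }
}

# internal: method-of-moments style starting values
phi_init <- function(blocks, design, map) {
  X <- blocks$X
  y <- blocks$y
  beta0 <- qr.coef(qr(X), y)
  r <- y - drop(X %*% ifelse(is.na(beta0), 0, beta0))
  phi <- numeric(length(map$names))
  names(phi) <- map$names
  if ("log_rb" %in% map$names) {
    pm <- tapply(r, design$patient[blocks$order], mean)
    icc <- stats::var(pm, na.rm = TRUE) / max(stats::var(r), 1e-12)
    icc <- min(max(icc, 0.02), 0.9)
    phi[["log_rb"]] <- 0.5 * log(icc / (1 - icc))
  }
  if ("log_ru" %in% map$names) phi[["log_ru"]] <- log(0.3)
  if (map$est_gamma) {
    if (map$ar) phi[["gamma_t"]] <- 0
    else {
      D <- design$grid$distance_matrix
      med <- stats::median(D[upper.tri(D)])
      phi[["gamma_t"]] <- log(log(2) / med)
    }
  }
  phi
}

#' Fit a spatial linear mixed effects model
#'
#' Maximises the profiled ML or REML objective over the transformed
#' variance parameters with a quasi-Newton (BFGS) optimiser and
#' numerical gradients, optionally from several jittered starting
#' values, then recovers the fixed effects by generalised least squares
#' and the random effects by their conditional expectations (BLUPs).
#'
#' @param data Long-format data frame (see [as_long_data()]).
#' @param spec An [slme_spec()].
#' @param grid A [sector_grid].
#' @param method `"REML"` (default) or `"ML"`.
#' @param control An [slme_control()].
#' @return An object of class `slme_fit` with components
#'   `coefficients`, `vcov`, `theta` (a [variance_components()]),
#'   `loglik_ml`, `loglik_reml`, `aic`, `bic`, `blups`,
#'   `converged`, `boundary`, `n_iter`, `grad_norm`, and bookkeeping
#'   fields. Standard accessors `coef()`, `vcov()`, `logLik()`,
#'   `summary()` apply.
#' @examples
#' \donttest{
#' set.seed(1)
#' dat <- simulate_scenario(scenario_config(n_patients = 50), rep_seed = 1)
#' sp <- slme_spec(thickness ~ risk + group + sector, random = "patient",
#'                 correlation = corr_spec("exponential"))
#' fit <- slme_fit(dat, sp, control = slme_control(n_starts = 1))
#' summary(fit)
#' }
#' @export
slme_fit <- function(data, spec, grid = etdrs_grid(),
                     method = c("REML", "ML"),
                     control = slme_control()) {
  method <- match.arg(method)
  design <- build_design(data, spec, grid)
  blocks <- compile_blocks(design)
  map <- phi_map(design)
  negobj <- make_objective(blocks, design, map, method)

  n_phi <- length(map$names)
  if (n_phi == 0) {
    opt <- list(par = numeric(0), value = negobj(numeric(0)),
                convergence = 0L, counts = c(`function` = 1L, gradient = 0L))
  } else {
    start0 <- phi_init(blocks, design, map)
    starts <- list(start0)
    if (control$n_starts > 1) {
      for (s in seq_len(control$n_starts - 1))
        starts[[s + 1]] <- start0 +
          stats::rnorm(n_phi, 0, control$jitter_sd)
    }
    opt <- NULL
    for (st in starts) {
      o <- tryCatch(
        stats::optim(st, negobj, method = "BFGS",
                     control = list(reltol = control$reltol,
                                    maxit = control$maxit)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(opt) || o$value < opt$value)) opt <- o
    }
    if (is.null(opt)) stop("optimisation failed from every starting value")
  }

  phi <- opt$par
  par <- phi_unpack(phi, map, design$spec)

  # final quantities on the unit residual scale
  Cfull <- resolve_correlation(design$spec$correlation, par$gamma, grid)
  pieces <- gls_pieces(blocks, unit_V_fun(blocks, par$r_b2, par$r_u2,
                                          Cfull, par$lambda))
  if (is.null(pieces)) stop("final covariance is not positive definite")
  N <- pieces$N
  p <- blocks$p
  Rx <- chol(pieces$XtX)
  beta <- drop(backsolve(Rx, backsolve(Rx, pieces$Xty, transpose = TRUE)))
  names(beta) <- colnames(design$X)
  rss <- max(pieces$yty - sum(beta * pieces$Xty), 1e-12)
  sigma2 <- if (method == "REML") rss / (N - p) else rss / N
  cov_beta <- sigma2 * chol2inv(Rx)
  dimnames(cov_beta) <- list(names(beta), names(beta))

  logdetXtX_unit <- 2 * sum(log(diag(Rx)))
  loglik_ml <- -0.5 * (N * log(2 * pi) + N * log(sigma2) + pieces$logdet +
                         rss / sigma2)
  loglik_reml <- -0.5 * ((N - p) * log(2 * pi) + (N - p) * log(sigma2) +
                           pieces$logdet + logdetXtX_unit + rss / sigma2)

  weight_ratios <- NULL
  if (!is.null(design$lambda_levels)) {
    weight_ratios <- par$lambda
    names(weight_ratios) <- design$lambda_levels
  }
  theta <- variance_components(
    sd_patient = sqrt(sigma2 * par$r_b2),
    sd_eye = sqrt(sigma2 * par$r_u2),
    sd_resid = sqrt(sigma2),
    gamma = if (design$spec$correlation$family == "independence") NA_real_
            else par$gamma,
    weight_ratios = weight_ratios)

  # honest convergence diagnostics: numerical gradient at the optimum
  grad_norm <- 0
  if (n_phi > 0) {
    g <- vapply(seq_len(n_phi), function(k) {
      h <- 1e-5 * (1 + abs(phi[k]))
      e <- numeric(n_phi); e[k] <- h
      (negobj(phi + e) - negobj(phi - e)) / (2 * h)
    }, numeric(1))
    grad_norm <- sqrt(sum(g^2))
  }
  boundary <- n_phi > 0 && any(abs(phi) > control$boundary_tol)
  converged <- opt$convergence == 0 &&
    grad_norm <= control$grad_tol * (1 + abs(opt$value))

  blups <- compute_blups(blocks, beta, par, Cfull)

  n_theta <- n_phi + 1L   # free variance parameters + sigma_s
  loglik <- if (method == "REML") loglik_reml else loglik_ml
  p_total <- p + n_theta
  n_eff <- if (method == "REML") N - p else N
  aic <- -2 * loglik + 2 * p_total
  bic <- -2 * loglik + p_total * log(n_eff)

  structure(list(
    coefficients = beta, vcov = cov_beta, theta = theta,
    loglik_ml = loglik_ml, loglik_reml = loglik_reml, loglik = loglik,
    aic = aic, bic = bic, n_obs = N, p_fixed = p, n_theta = n_theta,
    n_eff = n_eff, method = method, spec = design$spec, grid = grid,
    blups = blups, converged = converged, boundary = boundary,
    n_iter = unname(opt$counts[1]), grad_norm = grad_norm,
    phi = phi, sigma2 = sigma2,
    x_names = colnames(design$X), n_dropped = design$n_dropped,
    call = match.call()
  ), class = "slme_fit")
}

# internal: empirical-Bayes conditional means of the random intercepts.
# b_hat_i = sd_patient^2 1' H^-1 r_i and u_hat_ij = sd_eye^2 1' H^-1 r_i
# reduce on the unit residual scale to r_b2 * 1' V^-1 r_i and
# r_u2 * 1_eye' V^-1 r_i (the sigma^2 factors cancel).
compute_blups <- function(blocks, beta, par, Cfull) {
  b <- numeric(0)
  u <- numeric(0)
  p <- blocks$p
  for (pat in blocks$patterns) {
    V <- build_block_V(pat, par$r_b2, par$r_u2, Cfull, par$lambda)
    R <- chol(V)
    resid <- pat$Y - matrix(
      matrix(aperm(array(pat$Xflat, c(pat$n, p, pat$m)), c(1, 3, 2)),
             pat$n * pat$m, p) %*% beta, pat$n, pat$m)
    Vinv_r <- backsolve(R, backsolve(R, resid, transpose = TRUE))
    if (par$r_b2 > 0) {
      bb <- par$r_b2 * colSums(Vinv_r)
      names(bb) <- pat$patients
      b <- c(b, bb)
    }
    if (par$r_u2 > 0) {
      for (e in seq_along(pat$eye_spans)) {
        uu <- par$r_u2 * colSums(Vinv_r[pat$eye_spans[[e]], , drop = FALSE])
        names(uu) <- pat$eye_ids[e, ]
        u <- c(u, uu)
      }
    }
  }
  if (length(b)) b <- b[order(names(b))]
  if (length(u)) u <- u[order(names(u))]
  list(b = b, u = u)
}

#' Predicted random effects (BLUPs) of a fitted SLME model
#'
#' Returns the empirical-Bayes conditional means of the patient-level
#' intercepts `b_i` and the eye-within-patient intercepts `u_ij`,
#' evaluated at the estimated fixed effects and variance components.
#' Levels whose variance is zero (or absent from the model) yield an
#' empty vector.
#'
#' @param fitted An `slme_fit` object.
#' @return List with named numeric vectors `b` (per patient) and `u`
#'   (per eye, named `patient/eye`).
#' @export
predict_blups <- function(fitted) {
  stopifnot(inherits(fitted, "slme_fit"))
  fitted$blups
}

#' @export
coef.slme_fit <- function(object, ...) object$coefficients

#' @export
vcov.slme_fit <- function(object, ...) object$vcov

#' @export
logLik.slme_fit <- function(object, ...) {
  structure(object$loglik, df = object$p_fixed + object$n_theta,
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.slme_fit <- function(x, ...) {
  cat("Spatial linear mixed effects model (", x$method, ")\n", sep = "")
  cat("  Fixed:      ", deparse(x$spec$fixed), "\n")
  cat("  Random:     ", if (length(x$spec$random))
    paste(x$spec$random, collapse = " + ") else "(none)", "\n")
  cat("  Correlation:", x$spec$correlation$family, "\n")
  cat("  N =", x$n_obs, " logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7), "\n")
  cat("  Converged:", x$converged,
      if (x$boundary) " (boundary estimate)" else "", "\n")
  invisible(x)
}

#' @export
summary.slme_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std.Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.slme_fit"
  out
}

#' @export
print.summary.slme_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coef_table, digits = 4)
  cat("\n")
  print(x$fit$theta)
  invisible(x)
}
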