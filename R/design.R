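#' Build design matrices for an SLME model
#'
#' Constructs the fixed-effects design matrix `X` from the model formula
#' (with the `sector` factor baselined at the reference sector), the
#' response vector, and the grouping indices used to assemble the
#' random-effect and residual covariance. Rows with missing covariates
#' are dropped with a message (no imputation is performed).
#'
#' @param data A long-format data frame (see [as_long_data()]).
#' @param spec An [slme_spec()].
#' @param grid A [sector_grid].
#' @return An object of class `slme_design`: list with `X`, `y`,
#'   `patient`, `eye` (factors), `sector_pos` (positions in
#'   `grid$sector_ids`), `lambda_idx`/`lambda_levels` (heteroscedastic
#'   grouping, or `NULL`), `n_dropped`, and the originating `spec`/`grid`.
#' @export
build_design <- function(data, spec, grid = etdrs_grid()) {
  stopifnot(inherits(spec, "slme_spec"), inherits(grid, "sector_grid"))
  data <- as_long_data(data)
  bad <- !(data$sector_id %in% grid$sector_ids)
  if (any(bad))
    stop("unknown sector id(s): ",
         paste(unique(data$sector_id[bad]), collapse = ", "))
  ref <- spec$reference_sector
  if (!ref %in% grid$sector_ids)
    stop("reference sector '", ref, "' not in grid")
  data$sector <- factor(data$sector_id,
                        levels = c(ref, setdiff(grid$sector_ids, ref)))

  mf <- stats::model.frame(spec$fixed, data = data,
                           na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("build_design: dropped ", n_dropped,
            " row(s) with missing covariates")
    data <- data[keep, , drop = FALSE]
    mf <- mf[keep, , drop = FALSE]
  }
  X <- stats::model.matrix(stats::terms(mf), mf)
  y <- stats::model.response(mf)
  if (is.null(y)) stop("the fixed-effects formula must have a response")
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design matrix is rank deficient")

  lambda_idx <- NULL
  lambda_levels <- NULL
  if (!is.null(spec$weights_by)) {
    wcol <- data[[spec$weights_by]]
    if (is.null(wcol)) stop("weights column '", spec$weights_by, "' not found")
    wf <- factor(wcol)
    if (!is.null(spec$weights_reference)) {
      if (!spec$weights_reference %in% levels(wf))
        stop("weights reference level '", spec$weights_reference,
             "' not present")
      wf <- stats::relevel(wf, ref = spec$weights_reference)
    }
    lambda_idx <- as.integer(wf)
    lambda_levels <- levels(wf)
  }

  structure(list(
    X = X, y = as.numeric(y),
    patient = factor(data$patient_id),
    eye = factor(paste(data$patient_id, data$eye_id, sep = "/")),
    eye_id = as.character(data$eye_id),
    sector_pos = match(data$sector_id, grid$sector_ids),
    lambda_idx = lambda_idx, lambda_levels = lambda_levels,
    n_dropped = n_dropped, spec = spec, grid = grid
  ), class = "slme_design")
}

#' Random-intercept incidence matrices
#'
#' Returns the 0/1 incidence matrices mapping patient-level (`Z`) and
#' eye-level (`D`) random intercepts to rows of the design. Intended for
#' inspection and small problems; the likelihood machinery never forms
#' them.
#'
#' @param design An `slme_design`.
#' @return List with matrices `Z_patient` (n x n_patients) and `D_eye`
#'   (n x n_eyes).
#' @export
incidence_matrices <- function(design) {
  stopifnot(inherits(design, "slme_design"))
  onehot <- function(f) {
    m <- vapply(levels(f), function(l) as.numeric(f == l),
                numeric(length(f)))
    matrix(m, nrow = length(f), dimnames = list(NULL, levels(f)))
  }
  list(Z_patient = onehot(design$patient), D_eye = onehot(design$eye))
}

# --- internal: group rows into per-patient blocks and identical "patterns" --
#
# Rows are reordered (patient, eye, sector position). Patients whose block
# structure is identical (same eye layout, observed sectors and residual
# weight group per cell) share one covariance block, so the likelihood
# needs a single Cholesky factorisation per pattern and per parameter
# value. Y and X are stacked pattern-wise for vectorised whitening.
compile_blocks <- function(design) {
  ord <- order(design$patient, design$eye, design$sector_pos)
  X <- design$X[ord, , drop = FALSE]
  y <- design$y[ord]
  pat <- design$patient[ord]
  eye <- design$eye[ord]
  spos <- design$sector_pos[ord]
  lidx <- if (is.null(design$lambda_idx)) rep(1L, length(y))
          else design$lambda_idx[ord]
  p <- ncol(X)

  rows_by_pat <- split(seq_along(y), pat)
  keys <- vapply(rows_by_pat, function(rr) {
    paste(match(eye[rr], unique(eye[rr])), spos[rr], lidx[rr],
          sep = ":", collapse = ";")
  }, character(1))

  patterns <- lapply(split(seq_along(keys), keys), function(pids) {
    rr1 <- rows_by_pat[[pids[1]]]
    n_k <- length(rr1)
    m_k <- length(pids)
    eye_local <- match(eye[rr1], unique(eye[rr1]))
    eye_spans <- split(seq_len(n_k), eye_local)
    idx <- vapply(pids, function(j) rows_by_pat[[j]], integer(n_k))
    idx <- matrix(idx, nrow = n_k)
    Y <- matrix(y[idx], nrow = n_k)
    Xflat <- matrix(0, n_k, p * m_k)
    for (j in seq_len(m_k))
      Xflat[, ((j - 1) * p + 1):(j * p)] <- X[idx[, j], , drop = FALSE]
    eye_ids <- matrix(as.character(eye[idx]), nrow = n_k)[
      vapply(eye_spans, `[`, integer(1), 1), , drop = FALSE]
    list(n = n_k, m = m_k, eye_spans = eye_spans,
         sec_pos = spos[rr1], lam_idx = lidx[rr1],
         patients = names(rows_by_pat)[pids], eye_ids = eye_ids,
         idx = idx, Y = Y, Xflat = Xflat)
  })

  list(patterns = unname(patterns), p = p, N = length(y),
       order = ord, X = X, y = y,
       has_patient = "patient" %in% design$spec$random,
       has_eye = "eye" %in% design$spec$random,
       n_lambda = if (is.null(design$lambda_levels)) 1L
                  else length(design$lambda_levels))
}

# internal: one pattern's covariance block on the unit residual scale.
# V = r_b2 * J + blockdiag_eyes(r_u2 * J_eye + Lam C_sub Lam)
build_block_V <- function(pat, r_b2, r_u2, Cfull, lambda) {
  n <- pat$n
  lam <- lambda[pat$lam_idx]
  V <- matrix(if (r_b2 > 0) r_b2 else 0, n, n)
  for (sp in pat$eye_spans) {
    Csub <- Cfull[pat$sec_pos[sp], pat$sec_pos[sp], drop = FALSE]
    V[sp, sp] <- V[sp, sp] + Csub * tcrossprod(lam[sp]) + r_u2
  }
  V
}

#' Assemble the marginal covariance blocks of an SLME model
#'
#' Builds, for each patient, the covariance matrix
#' `H_i = sd_patient^2 J + blockdiag_eyes(sd_eye^2 J_eye +
#' sd_resid^2 Lambda C Lambda)` over that patient's observed (eye,
#' sector) cells; eyes with missing sectors get the corresponding
#' principal sub-matrix of the kernel correlation.
#'
#' @param theta A [variance_components()]. Its `weight_ratios` (if any)
#'   must be named by the levels of the `weights_by` column.
#' @param data Long-format data frame.
#' @param spec An [slme_spec()].
#' @param grid A [sector_grid].
#' @return List with `blocks` (named list of per-patient symmetric PD
#'   matrices, rows ordered by eye then sector position) and `row_map`
#'   (data frame mapping original data rows to block positions).
#' @export
assemble_covariance <- function(theta, data, spec, grid = etdrs_grid()) {
  stopifnot(inherits(theta, "variance_components"))
  design <- build_design(data, spec, grid)
  blocks <- compile_blocks(design)
  Cfull <- resolve_correlation(spec$correlation, theta$gamma, grid)
  lambda <- resolve_lambda(theta, design$lambda_levels)
  out <- list()
  row_map <- data.frame(row = integer(0), patient = character(0),
                        block_row = integer(0))
  for (pat in blocks$patterns) {
    V <- build_block_V(pat, theta$sd_patient^2 / theta$sd_resid^2,
                       theta$sd_eye^2 / theta$sd_resid^2, Cfull, lambda)
    H <- theta$sd_resid^2 * V
    for (j in seq_len(pat$m)) {
      out[[pat$patients[j]]] <- H
      row_map <- rbind(row_map, data.frame(
        row = blocks$order[pat$idx[, j]],
        patient = pat$patients[j],
        block_row = seq_len(pat$n)))
    }
  }
  out <- out[order(names(out))]
  list(blocks = out, row_map = row_map[order(row_map$row), ])
}

# internal: correlation matrix over the full grid for given family/gamma.
# Gaussian/exponential kernels are PD by construction, so the eigenvalue
# safeguard is skipped in this hot path; spherical and AR go through the
# safeguarded builder.
resolve_correlation <- function(cspec, gamma, grid) {
  fam <- cspec$family
  n <- length(grid$sector_ids)
  if (fam == "independence") return(diag(n))
  if (is.na(gamma)) stop("kernel parameter 'gamma' is not set")
  if (fam %in% c("gaussian", "exponential")) {
    D <- grid$distance_matrix
    C <- if (fam == "gaussian") exp(-gamma * D^2) else exp(-gamma * D)
    diag(C) <- 1
    return(C)
  }
  correlation_matrix(corr_spec(fam, gamma), grid)
}

# internal: per-group residual SD ratios aligned with lambda_levels
resolve_lambda <- function(theta, lambda_levels) {
  if (is.null(lambda_levels)) return(1)
  wr <- theta$weight_ratios
  if (is.null(wr)) return(rep(1, length(lambda_levels)))
  if (!all(lambda_levels %in% names(wr)))
    stop("weight_ratios must name all levels: ",
         paste(lambda_levels, collapse = ", "))
  as.numeric(wr[lambda_levels])
}
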