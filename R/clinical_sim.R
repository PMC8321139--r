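#' Configure the synthetic clinical-data generator
#'
#' Generates nested two-eye datasets with the structure of a maculopathy
#' screening study: three diagnosis groups (healthy controls, diabetic
#' eyes without maculopathy M0, diabetic eyes with maculopathy M1),
#' up to two eyes per patient, nine sectors per eye, a patient-level
#' random intercept, an eye-within-patient intercept, and residuals with
#' exponential spatial correlation and heteroscedastic per-group scale.
#'
#' Default variance components are anchored to fitted values of this
#' model class on real screening data: between-patient SD 18.34 um,
#' between-eye SD 1.45 um, residual SD 23.8 um for the reference
#' (maculopathy) group with ratios 0.537 (M0) and 0.459 (healthy), and
#' exponential rate 1.4487 per mm. Group mean profiles follow the
#' typical macular topography (inner ring thickest, CS thinnest) with
#' the maculopathy profile uniformly thickest and the healthy profile
#' between the two diabetic groups; age enters with a -0.2 um/year
#' slope.
#'
#' @param n_healthy,n_m0,n_m1 Patients per diagnosis group (group is
#'   assigned at patient level; both eyes share it).
#' @param two_eye_prob Probability that a patient contributes both eyes.
#' @param missing_sector_rate Per-cell completely-at-random missingness.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param age_effect Slope of thickness on age (um/year).
#' @param group_profiles 3 x 9 matrix (rows healthy, M0, M1; columns the
#'   grid sectors) of mean thickness at the mean age.
#' @param sd_patient,sd_eye,sd_resid,gamma_e Variance components
#'   (`sd_resid` applies to the reference group M1).
#' @param weight_ratios Named residual SD ratios for
#'   `c(healthy, M0, M1)`; M1 is the reference at 1.
#' @param seed Integer seed; generation is deterministic given it.
#' @return An object of class `clinical_sim_config`.
#' @export
clinical_sim_config <- function(n_healthy = 50, n_m0 = 150, n_m1 = 150,
                                two_eye_prob = 0.84,
                                missing_sector_rate = 0.02,
                                age_mean = 54, age_sd = 15,
                                age_range = c(20, 86), age_effect = -0.2,
                                group_profiles = NULL,
                                sd_patient = 18.34, sd_eye = 1.45,
                                sd_resid = 23.8, gamma_e = 1.4487,
                                weight_ratios = c(healthy = 0.459,
                                                  M0 = 0.537, M1 = 1),
                                seed = 20160331) {
  stopifnot(two_eye_prob >= 0, two_eye_prob <= 1,
            missing_sector_rate >= 0, missing_sector_rate < 1,
            sd_patient >= 0, sd_eye >= 0, sd_resid > 0, gamma_e > 0,
            all(weight_ratios > 0))
  if (is.null(group_profiles)) {
    base <- c(CS = 283, SI = 318, TI = 312, II = 316, NI = 314,
              SO = 300, TO = 294, IO = 298, NO = 296)
    group_profiles <- rbind(healthy = base, M0 = base - 2, M1 = base + 4.5)
  }
  structure(list(n_healthy = n_healthy, n_m0 = n_m0, n_m1 = n_m1,
                 two_eye_prob = two_eye_prob,
                 missing_sector_rate = missing_sector_rate,
                 age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, age_effect = age_effect,
                 group_profiles = group_profiles,
                 sd_patient = sd_patient, sd_eye = sd_eye,
                 sd_resid = sd_resid, gamma_e = gamma_e,
                 weight_ratios = weight_ratios, seed = seed),
            class = "clinical_sim_config")
}

#' Generate a synthetic nested two-eye clinical dataset
#'
#' Draws patients with `b_i ~ N(0, sd_patient^2)`, eyes with
#' `u_ij ~ N(0, sd_eye^2)`, and per-eye residual vectors from
#' `N(0, sd_resid^2 lambda_g^2 C(gamma_e))` over the grid, then applies
#' completely-at-random sector missingness. Both lateralities occur;
#' centroid distances are reflection-invariant, so left and right eyes
#' share one correlation matrix.
#'
#' @param config A [clinical_sim_config()].
#' @param grid A [sector_grid].
#' @return A `long_data` data frame with columns `patient_id`, `eye_id`,
#'   `sector_id`, `group`, `age`, `laterality`, `thickness`.
#' @export
generate_clinical <- function(config, grid = etdrs_grid()) {
  stopifnot(inherits(config, "clinical_sim_config"))
  set.seed(config$seed)
  ids <- grid$sector_ids
  k <- length(ids)
  prof <- config$group_profiles[, ids, drop = FALSE]
  groups <- c("healthy", "M0", "M1")
  stopifnot(all(rownames(prof) == groups))

  n <- config$n_healthy + config$n_m0 + config$n_m1
  group <- factor(rep(groups, c(config$n_healthy, config$n_m0,
                                config$n_m1)), levels = groups)
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi),
                      config$age_mean, config$age_sd)
  b <- stats::rnorm(n, 0, config$sd_patient)
  n_eyes <- 1L + stats::rbinom(n, 1, config$two_eye_prob)
  first_od <- stats::runif(n) < 0.5

  C <- resolve_correlation(corr_spec("exponential"), config$gamma_e, grid)
  Rt <- t(chol(C))
  lam <- config$weight_ratios[as.character(group)]

  out <- vector("list", n)
  pid <- sprintf("p%04d", seq_len(n))
  for (i in seq_len(n)) {
    lats <- if (n_eyes[i] == 2) c("OD", "OS")
            else if (first_od[i]) "OD" else "OS"
    ey <- lapply(lats, function(lat) {
      u <- stats::rnorm(1, 0, config$sd_eye)
      eps <- config$sd_resid * lam[i] * drop(Rt %*% stats::rnorm(k))
      mu <- prof[as.character(group[i]), ] +
        config$age_effect * (age[i] - config$age_mean)
      data.frame(patient_id = pid[i],
                 eye_id = paste0(pid[i], "_", lat),
                 sector_id = ids,
                 group = group[i], age = age[i],
                 laterality = if (lat == "OD") "right" else "left",
                 thickness = mu + b[i] + u + eps)
    })
    out[[i]] <- do.call(rbind, ey)
  }
  dat <- do.call(rbind, out)
  rownames(dat) <- NULL
  if (config$missing_sector_rate > 0) {
    keep <- stats::runif(nrow(dat)) >= config$missing_sector_rate
    dat <- dat[keep, , drop = FALSE]
  }
  as_long_data(dat)
}
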