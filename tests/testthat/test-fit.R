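test_that("REML recovers the generating variance components and kernel rate", {
  cfg <- scenario_config(gamma_e = 0.5, n_patients = 300,
                         sd_random_intercept = 18, sd_resid = 10)
  dat <- simulate_scenario(cfg, rep_seed = 2024)
  sp <- slme_spec(thickness ~ risk + group + sector + group:sector,
                  random = "patient", correlation = corr_spec("exponential"))
  fit <- slme_fit(dat, sp, control = slme_control(n_starts = 1))
  expect_true(fit$converged)
  expect_equal(fit$theta$sd_patient, 18, tolerance = 0.15)
  expect_equal(fit$theta$sd_resid, 10, tolerance = 0.15)
  expect_equal(fit$theta$gamma, 0.5, tolerance = 0.25)
  expect_equal(coef(fit)[["risk"]], -0.3,
               tolerance = 10 * sqrt(vcov(fit)["risk", "risk"]) / 0.3)
})

test_that("independence with no random effects reduces exactly to OLS", {
  d <- quick_scenario_data(n_patients = 20, gamma_e = NA, seed = 8)
  sp <- slme_spec(thickness ~ risk + sector, random = character(0),
                  correlation = corr_spec("independence"))
  fit <- slme_fit(d, sp, method = "REML")
  d$sector <- factor(d$sector_id, levels = etdrs_grid()$sector_ids)
  ols <- lm(thickness ~ risk + sector, data = d)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-10)
  expect_equal(fit$theta$sd_resid, summary(ols)$sigma, tolerance = 1e-9)
  expect_equal(vcov(fit), vcov(ols), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a zero eye-level variance drives the estimate to the boundary and is flagged", {
  cfg <- clinical_sim_config(n_healthy = 20, n_m0 = 40, n_m1 = 40,
                             two_eye_prob = 1, missing_sector_rate = 0,
                             sd_eye = 0, seed = 5)
  dat <- generate_clinical(cfg)
  sp <- slme_spec(thickness ~ group + sector, random = c("patient", "eye"),
                  correlation = corr_spec("exponential"))
  fit <- slme_fit(dat, sp, control = slme_control(n_starts = 1))
  expect_lt(fit$theta$sd_eye, 0.1)
  expect_true(fit$boundary)
})

test_that("fits are deterministic given data and (for multi-start) the RNG seed", {
  d <- quick_scenario_data(n_patients = 30, gamma_e = 0.5, seed = 4)
  sp <- slme_spec(thickness ~ risk + group + sector, random = "patient",
                  correlation = corr_spec("exponential"))
  f1 <- slme_fit(d, sp, control = slme_control(n_starts = 1))
  f2 <- slme_fit(d, sp, control = slme_control(n_starts = 1))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$theta, f2$theta)
  set.seed(99); g1 <- slme_fit(d, sp, control = slme_control(n_starts = 3))
  set.seed(99); g2 <- slme_fit(d, sp, control = slme_control(n_starts = 3))
  expect_identical(coef(g1), coef(g2))
})

test_that("the REML/ML relationship holds on every fitted model", {
  d <- quick_scenario_data(n_patients = 25, gamma_e = 0.5, seed = 6, sd_b = 5)
  for (fam in c("independence", "exponential")) {
    sp <- slme_spec(thickness ~ risk + group + sector, random = "patient",
                    correlation = corr_spec(fam))
    fit <- slme_fit(d, sp, control = slme_control(n_starts = 1))
    p <- fit$p_fixed
    logdet_xhx <- -as.numeric(
      determinant(vcov(fit), logarithm = TRUE)$modulus)
    expect_equal(fit$loglik_reml,
                 fit$loglik_ml - 0.5 * logdet_xhx + (p / 2) * log(2 * pi),
                 tolerance = 1e-7, info = fam)
  }
})

test_that("patient BLUPs are the closed-form shrunken residual means", {
  d <- tiny_data(8, n_eyes = 1, sd = 3, patient_shift = 4, seed = 21)
  sp <- slme_spec(thickness ~ 1, random = "patient",
                  correlation = corr_spec("independence"))
  fit <- slme_fit(d, sp, control = slme_control(n_starts = 1))
  th <- fit$theta
  shrink <- th$sd_patient^2 / (th$sd_patient^2 + th$sd_resid^2 / 9)
  blups <- predict_blups(fit)
  for (pid in unique(d$patient_id)) {
    rbar <- mean(d$thickness[d$patient_id == pid]) - coef(fit)[[1]]
    expect_equal(unname(blups$b[pid]), shrink * rbar, tolerance = 1e-6)
  }
  expect_equal(mean(blups$b), 0, tolerance = 0.5)
})

test_that("BLUPs vanish when the patient variance is (near) zero", {
  d <- tiny_data(10, n_eyes = 1, sd = 5, patient_shift = 0, seed = 31)
  sp <- slme_spec(thickness ~ 1, random = "patient",
                  correlation = corr_spec("independence"))
  fit <- slme_fit(d, sp, control = slme_control(n_starts = 1))
  if (length(predict_blups(fit)$b))
    expect_lt(max(abs(predict_blups(fit)$b)), 1)
})

test_that("non-spatial equal-weight fits agree with nlme", {
  cfg <- clinical_sim_config(n_healthy = 20, n_m0 = 30, n_m1 = 30,
                             two_eye_prob = 1, missing_sector_rate = 0,
                             sd_eye = 8, seed = 17)
  dat <- generate_clinical(cfg)
  sp <- slme_spec(thickness ~ age + group + sector,
                  random = c("patient", "eye"),
                  correlation = corr_spec("independence"))
  fit <- slme_fit(dat, sp, control = slme_control(n_starts = 1))

  dat$sector <- factor(dat$sector_id, levels = etdrs_grid()$sector_ids)
  ref <- nlme::lme(thickness ~ age + group + sector, data = dat,
                   random = ~ 1 | patient_id / eye_id, method = "REML",
                   control = nlme::lmeControl(tolerance = 1e-10))
  expect_equal(unname(coef(fit)), unname(nlme::fixef(ref)),
               tolerance = 1e-4)
  vc <- nlme::VarCorr(ref)
  expect_equal(fit$theta$sd_patient,
               as.numeric(vc["(Intercept)", "StdDev"][1]), tolerance = 1e-4)
  expect_equal(fit$theta$sd_resid,
               as.numeric(vc["Residual", "StdDev"]), tolerance = 1e-4)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  expect_equal(fit$theta$sd_eye, sds[4], tolerance = 1e-3)
  expect_equal(sqrt(diag(vcov(fit))), sqrt(diag(vcov(ref))),
               tolerance = 1e-3, ignore_attr = TRUE)
})
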