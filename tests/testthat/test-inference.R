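fit_small <- local({
  f <- NULL
  function() {
    if (is.null(f)) {
      d <- quick_scenario_data(n_patients = 40, gamma_e = 0.5, seed = 12)
      sp <- slme_spec(thickness ~ risk + group + sector + group:sector,
                      random = "patient",
                      correlation = corr_spec("exponential"))
      f <<- slme_fit(d, sp, control = slme_control(n_starts = 1))
    }
    f
  }
})

test_that("single-coefficient Wald tests follow the normal reference", {
  fit <- fit_small()
  b <- coef(fit)[["risk"]]
  se <- sqrt(vcov(fit)["risk", "risk"])
  w <- wald_test(fit, "risk")
  expect_equal(w$statistic, b / se)
  expect_equal(w$p_value, 2 * pnorm(-abs(b / se)))
  # a coefficient two SEs from its null gives z = 2, p ~ 0.0455
  w2 <- wald_test(fit, "risk", null = b - 2 * se)
  expect_equal(w2$statistic, 2)
  expect_equal(w2$p_value, 0.0455, tolerance = 1e-3)
  # testing against its own value: statistic 0, p = 1
  w0 <- wald_test(fit, "risk", null = b)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
})

test_that("joint Wald statistics match the quadratic form oracle", {
  fit <- fit_small()
  idx <- grep("group.*:sector", names(coef(fit)), value = TRUE)
  w <- wald_test(fit, idx)
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx]
  W_oracle <- drop(t(b) %*% solve(V) %*% b)
  expect_equal(w$statistic, W_oracle, tolerance = 1e-9)
  expect_equal(w$df, length(idx))
  expect_equal(w$p_value, pchisq(W_oracle, length(idx), lower.tail = FALSE))
  wf <- wald_test(fit, idx, test = "F")
  expect_equal(wf$statistic, W_oracle / length(idx), tolerance = 1e-9)
  expect_error(wald_test(fit, "not_a_coef"), "unknown")
  expect_error(wald_test(fit, character(0)), "no coefficients")
})

test_that("likelihood-ratio tests behave on nested ML fits", {
  d <- quick_scenario_data(n_patients = 40, gamma_e = 0.5, seed = 13)
  sp_full <- slme_spec(thickness ~ risk + group + sector, random = "patient",
                       correlation = corr_spec("exponential"))
  sp_red <- slme_spec(thickness ~ risk + sector, random = "patient",
                      correlation = corr_spec("exponential"))
  f_full <- slme_fit(d, sp_full, method = "ML",
                     control = slme_control(n_starts = 1))
  f_red <- slme_fit(d, sp_red, method = "ML",
                    control = slme_control(n_starts = 1))
  lrt <- slme_lrt(f_full, f_red)
  expect_equal(lrt$statistic,
               max(0, 2 * (f_full$loglik - f_red$loglik)))
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)
  expect_false(lrt$boundary_caveat)
  # REML comparisons with different fixed effects are refused
  r_full <- slme_fit(d, sp_full, control = slme_control(n_starts = 1))
  r_red <- slme_fit(d, sp_red, control = slme_control(n_starts = 1))
  expect_error(slme_lrt(r_full, r_red), "identical fixed effects")
  expect_error(slme_lrt(f_full, f_full), "nested")
})

test_that("the boundary LRT for the eye effect is conservative under the null", {
  # sd_eye = 0 in truth: naive chi-square rejection should stay <= alpha
  n_rej <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    cfg <- clinical_sim_config(n_healthy = 10, n_m0 = 15, n_m1 = 15,
                               two_eye_prob = 1, missing_sector_rate = 0,
                               sd_eye = 0, gamma_e = 2, seed = 7000 + r)
    dat <- generate_clinical(cfg)
    sp_full <- slme_spec(thickness ~ group, random = c("patient", "eye"),
                         correlation = corr_spec("independence"))
    sp_red <- slme_spec(thickness ~ group, random = "patient",
                        correlation = corr_spec("independence"))
    f_full <- slme_fit(dat, sp_full, control = slme_control(n_starts = 1))
    f_red <- slme_fit(dat, sp_red, control = slme_control(n_starts = 1))
    lrt <- slme_lrt(f_full, f_red)
    expect_true(lrt$boundary_caveat)
    if (lrt$p_value < 0.05) n_rej <- n_rej + 1
  }
  # binomial slack above alpha = 0.05 at 30 replications
  expect_lte(n_rej / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("information criteria follow their definitions", {
  fit <- fit_small()
  p_total <- fit$p_fixed + fit$n_theta
  ic <- information_criteria(fit)
  expect_equal(ic[["aic"]], -2 * fit$loglik + 2 * p_total)
  expect_equal(ic[["bic"]], -2 * fit$loglik + p_total * log(fit$n_eff))
  icp <- information_criteria(fit, bic_doubled_penalty = TRUE)
  expect_equal(icp[["bic"]] - ic[["bic"]], p_total * log(fit$n_eff))
  # arithmetic spot checks via a stubbed fit object
  fake <- fit
  fake$loglik <- -10
  fake$p_fixed <- 2L; fake$n_theta <- 1L
  fake$n_eff <- exp(2)
  expect_equal(information_criteria(fake)[["aic"]], 26)
  expect_equal(information_criteria(fake)[["bic"]], 26)
})
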