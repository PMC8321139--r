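iid_spec <- function() slme_spec(thickness ~ 1, random = character(0),
                                 correlation = corr_spec("independence"))

one_cell_per_patient <- function(y) {
  as_long_data(data.frame(patient_id = paste0("p", seq_along(y)),
                          eye_id = paste0("p", seq_along(y), "_e1"),
                          sector_id = "CS", thickness = y))
}

test_that("the log-likelihood reduces to the normal density in the iid case", {
  d1 <- one_cell_per_patient(0)
  th1 <- variance_components(0, 0, 1)
  expect_equal(slme_loglik_ml(0, th1, d1, iid_spec()),
               -0.5 * log(2 * pi), tolerance = 1e-9)
  expect_equal(slme_loglik_ml(0, th1, d1, iid_spec()), dnorm(0, log = TRUE))

  d <- tiny_data(3, sd = 2, seed = 11)
  th <- variance_components(0, 0, 2)
  expect_equal(slme_loglik_ml(280, th, d, iid_spec()),
               sum(dnorm(d$thickness, 280, 2, log = TRUE)))
})

test_that("at a perfect fit, rescaling the residual variance only moves the log-determinant", {
  d <- one_cell_per_patient(c(5, 5, 5))
  sp <- iid_spec()
  l1 <- slme_loglik_ml(5, variance_components(0, 0, 1), d, sp)
  l2 <- slme_loglik_ml(5, variance_components(0, 0, sqrt(2)), d, sp)
  expect_equal(l1 - l2, -0.5 * 3 * log(1 / 2))  # -1/2 (logdet1 - logdet2)
})

test_that("GLS equals OLS under identity covariance", {
  d <- tiny_data(3, sd = 3, seed = 7)
  g <- slme_gls(variance_components(0, 0, 1), d, iid_spec())
  ols <- lm(thickness ~ 1, data = d)
  expect_equal(unname(g$beta), unname(coef(ols)), tolerance = 1e-10)

  d4 <- one_cell_per_patient(c(1, 2, 3, 4))
  g4 <- slme_gls(variance_components(0, 0, 1), d4, iid_spec())
  expect_equal(unname(g4$cov_beta[1, 1]), 1 / 4)
})

test_that("heteroscedastic GLS reproduces the weighted mean", {
  d <- one_cell_per_patient(c(1, 3))
  d$grp <- c("a", "b")
  sp <- slme_spec(thickness ~ 1, random = character(0),
                  correlation = corr_spec("independence"),
                  weights_by = "grp", weights_reference = "a")
  th <- variance_components(0, 0, 1, weight_ratios = c(a = 1, b = 2))
  g <- slme_gls(th, d, sp)                 # H = diag(1, 4)
  expect_equal(unname(g$beta), 1.4)        # (1 + 3/4) / (1 + 1/4)
  expect_equal(unname(g$cov_beta[1, 1]), 0.8)
})

test_that("iid intercept-only fits recover the closed-form variance estimators", {
  d <- one_cell_per_patient(c(1, 2, 3))
  reml <- slme_fit(d, iid_spec(), method = "REML")
  ml <- slme_fit(d, iid_spec(), method = "ML")
  expect_equal(reml$theta$sd_resid^2, 1.0, tolerance = 1e-8)   # divisor n-1
  expect_equal(ml$theta$sd_resid^2, 2 / 3, tolerance = 1e-8)   # divisor n
  expect_equal(unname(coef(reml)), 2, tolerance = 1e-10)
})

test_that("the REML objective equals ML plus the fixed-effects correction", {
  d <- quick_scenario_data(n_patients = 15, gamma_e = 0.5, seed = 3)
  sp <- slme_spec(thickness ~ risk + group + sector, random = "patient",
                  correlation = corr_spec("exponential", 0.5))
  th <- variance_components(sd_patient = 4, sd_eye = 0, sd_resid = 9,
                            gamma = 0.5)
  g <- slme_gls(th, d, sp)
  lml <- slme_loglik_ml(g$beta, th, d, sp)
  lr <- slme_loglik_reml(th, d, sp)
  p <- length(g$beta)
  logdet_xhx <- -determinant(g$cov_beta, logarithm = TRUE)$modulus
  expect_equal(lr, lml - 0.5 * as.numeric(logdet_xhx) + (p / 2) * log(2 * pi),
               tolerance = 1e-8)
})

test_that("the restricted likelihood is invariant to fixed-effects reparametrisation", {
  d <- quick_scenario_data(n_patients = 12, gamma_e = NA, seed = 5)
  th <- variance_components(2, 0, 10)
  sp_a <- slme_spec(thickness ~ group, random = "patient",
                    correlation = corr_spec("independence"))
  sp_b <- slme_spec(thickness ~ 0 + group, random = "patient",
                    correlation = corr_spec("independence"))
  expect_equal(slme_loglik_reml(th, d, sp_a),
               slme_loglik_reml(th, d, sp_b), tolerance = 1e-9)
})
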