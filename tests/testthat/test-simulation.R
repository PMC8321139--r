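test_that("the noiseless limit returns the fixed-effect surface exactly", {
  cfg <- scenario_config(n_patients = 10, gamma_e = NA,
                         sd_random_intercept = 0, sd_resid = 0)
  d <- simulate_scenario(cfg, rep_seed = 1)
  ids <- etdrs_grid()$sector_ids
  inner <- ids %in% c("SI", "NI", "II", "TI")
  for (i in seq_len(5)) {
    rows <- d[d$patient_id == sprintf("p%04d", i), ]
    m1 <- as.numeric(rows$group[1] == "M1")
    expected <- cfg$true_beta0 + cfg$true_beta1 * rows$risk[1] +
      cfg$true_beta2 * m1 + cfg$sector_effects[ids] +
      cfg$interaction_inner * inner * m1
    expect_equal(rows$thickness, unname(expected))
  }
})

test_that("scenario simulation is deterministic in the replication seed", {
  cfg <- scenario_config(scenario = 2, n_patients = 30)
  expect_identical(simulate_scenario(cfg, 7), simulate_scenario(cfg, 7))
  expect_false(identical(simulate_scenario(cfg, 7)$thickness,
                         simulate_scenario(cfg, 8)$thickness))
})

test_that("scenario structure matches its configuration", {
  cfg <- scenario_config(scenario = 3, n_patients = 40)
  expect_equal(cfg$gamma_e, 0.1)
  d <- simulate_scenario(cfg, 1)
  expect_equal(nrow(d), 40 * 9)
  expect_equal(
    sum(tapply(as.character(d$group), d$patient_id, `[`, 1) == "M0"),
    28)  # 70% of 40
  expect_true(all(d$risk >= 20 & d$risk <= 86))
  expect_error(scenario_config(prop_m0 = 1.2))
  expect_error(scenario_config(scenario = 9))
})

test_that("simulated residual correlation matches the kernel (moment oracle)", {
  g <- etdrs_grid()
  cfg <- scenario_config(gamma_e = 0.1, n_patients = 3000,
                         sd_random_intercept = 0)
  d <- simulate_scenario(cfg, rep_seed = 99)
  ids <- g$sector_ids
  inner <- ids %in% c("SI", "NI", "II", "TI")
  m1 <- as.numeric(d$group == "M1")
  mu <- cfg$true_beta0 + cfg$true_beta1 * d$risk + cfg$true_beta2 * m1 +
    rep(cfg$sector_effects[ids], 3000) +
    cfg$interaction_inner * rep(inner, 3000) * m1
  resid <- matrix(d$thickness - mu, nrow = 9)
  dmat <- g$distance_matrix
  # closest pair: CS and any inner sector at 1 mm
  r_emp <- cor(resid["CS" == ids, ], resid["SI" == ids, ])
  expect_equal(r_emp, exp(-0.1 * dmat["CS", "SI"]), tolerance = 0.03)
  r_far <- cor(resid[which(ids == "SO"), ], resid[which(ids == "IO"), ])
  expect_equal(r_far, exp(-0.1 * dmat["SO", "IO"]), tolerance = 0.05)
})

test_that("a small Monte-Carlo run produces a consistent summary", {
  cfg <- scenario_config(scenario = 1, n_patients = 60, seed = 314)
  s <- run_scenario(cfg, n_reps = 6)
  expect_s3_class(s, "mc_summary")
  expect_equal(s$n_done + s$n_failed, 6)
  expect_true(all(s$table$cp_pct >= 0 & s$table$cp_pct <= 100))
  expect_true(all(s$table$sd >= 0))
  expect_equal(nrow(s$table), 4)
  expect_true(all(s$power >= 0 & s$power <= 100))
  out <- capture.output(print(s))
  expect_true(any(grepl("%", out)))   # CP rendered as percentages
})

test_that("rendered tables round-trip through CSV", {
  cfg <- scenario_config(scenario = 1, n_patients = 60, seed = 314)
  s <- run_scenario(cfg, n_reps = 4)
  f <- tempfile(fileext = ".csv")
  tab <- render_mc_tables(s, csv_path = f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$quantity, tab$quantity)
  expect_equal(back[["spatial.beta1"]], tab[["spatial.beta1"]],
               tolerance = 1e-12)
  unlink(f)
})

test_that("scenario configurations round-trip through YAML", {
  cfg <- scenario_config(scenario = 2, n_patients = 77, seed = 5)
  f <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  cfg2 <- read_scenario_config(f)
  expect_equal(cfg2$gamma_e, 0.5)
  expect_equal(cfg2$n_patients, 77)
  expect_equal(cfg2$sector_effects, cfg$sector_effects)
  expect_identical(simulate_scenario(cfg, 3), simulate_scenario(cfg2, 3))
  unlink(f)
})
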