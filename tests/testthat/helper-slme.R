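# Shared fixtures, built in code.

# tiny long dataset: n_pat patients, eyes per patient, sectors per eye,
# iid N(mu, sd) responses plus optional per-patient shifts
tiny_data <- function(n_pat = 3, n_eyes = 1, sectors = etdrs_grid()$sector_ids,
                      mu = 280, sd = 1, patient_shift = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_pat)) {
    for (j in seq_len(n_eyes)) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = paste0("p", i),
        eye_id = paste0("p", i, "_e", j),
        sector_id = sectors,
        thickness = mu + patient_shift * i +
          stats::rnorm(length(sectors), 0, sd))
    }
  }
  as_long_data(do.call(rbind, rows))
}

# a two-sector line grid at unit spacing (reference sector "A")
line_grid <- function(n = 2, spacing = 1) {
  ids <- LETTERS[seq_len(n)]
  sector_grid(ids, x_mm = spacing * (seq_len(n) - 1), y_mm = rep(0, n))
}

# one-level generator matching the scenario model but tiny, for fit tests
quick_scenario_data <- function(n_patients = 60, gamma_e = 0.5, seed = 1,
                                sd_b = 0, sd_resid = 10) {
  cfg <- scenario_config(gamma_e = gamma_e, n_patients = n_patients,
                         sd_random_intercept = sd_b, sd_resid = sd_resid)
  simulate_scenario(cfg, rep_seed = seed)
}
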