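test_that("FRET efficiency from lifetimes inverts the lifetime-shift relation", {
  expect_equal(efficiency_from_lifetimes(3.12, 3.12), 0)
  expect_equal(efficiency_from_lifetimes(3.12, 1.56), 0.5)
  expect_equal(efficiency_from_lifetimes(3.12, 2.368), 0.241,
               tolerance = 1e-3)
  # round trip with expected_lifetime_shift at machine precision
  for (E in c(0.05, 0.241, 0.64)) {
    tau_fret <- expected_lifetime_shift(3.2, E)$tau_fret
    expect_equal(efficiency_from_lifetimes(3.2, tau_fret), E,
                 tolerance = 1e-14)
  }
  expect_warning(E <- efficiency_from_lifetimes(3.0, 3.1), "negative")
  expect_lt(E, 0)
  expect_error(efficiency_from_lifetimes(0, 1), "positive")
})

test_that("Z'-factor arithmetic, bounds and invariances", {
  expect_equal(z_factor(4, 0, 2.8, 0), 1)
  expect_equal(z_factor(4.04, 0.08, 2.80, 0.08), 1 - 0.48 / 1.24,
               tolerance = 1e-12)
  # scale invariance under common positive rescaling
  z <- z_factor(4.04, 0.08, 2.80, 0.08)
  for (c in c(0.1, 3, 1000))
    expect_equal(z_factor(c * 4.04, c * 0.08, c * 2.80, c * 0.08), z,
                 tolerance = 1e-12)
  # strictly decreasing in each sigma, never above 1
  expect_lt(z_factor(4, 0.1, 2.8, 0.05), z_factor(4, 0.05, 2.8, 0.05))
  expect_lt(z_factor(4, 0.05, 2.8, 0.1), z_factor(4, 0.05, 2.8, 0.05))
  expect_true(z_factor(4, 0.5, 3.9, 0.5) < 0)  # tiny shift: negative Z'
  expect_error(z_factor(3, 0.1, 3, 0.1), "undefined separation")
})

test_that("evaluate_assay implements the day-repeat design", {
  cfg <- synthetic_study_config(pair_name = "Clv-mCh",
                                measurement = "gaussian", rng_seed = 101)
  st <- generate_study(cfg)
  donor <- st[st$construct == "donor_alone", ]
  pair <- st[st$construct == "Clv-mCh", ]
  ev <- evaluate_assay(donor, pair, "static")
  expect_s3_class(ev, "assay_evaluation")
  expect_identical(ev$n_days, 3L)
  # per-day Z' recomputable from the per-day mu/sigma
  pd <- ev$per_day
  expect_equal(pd$Zprime,
               z_factor(pd$mu_max, pd$sigma_max, pd$mu_min, pd$sigma_min))
  # E recovered near the generating truth
  expect_lt(abs(ev$E_mean - cfg$E_true), 3 * ev$E_sd / sqrt(ev$n_days))
  # static mode on single-timepoint data equals dynamic mode
  ev_dyn <- evaluate_assay(donor, pair, "dynamic")
  expect_equal(ev_dyn$E_mean, ev$E_mean)
  expect_equal(ev_dyn$Zprime_mean, ev$Zprime_mean)
})

test_that("a null assay (identical populations) gives E ~ 0 and deeply negative Z'", {
  cfg <- synthetic_study_config(pair_name = "null", E_true = 0,
                                E_cell_sd = 0,
                                measurement = "gaussian", rng_seed = 7)
  st <- generate_study(cfg)
  suppressWarnings(
    ev <- evaluate_assay(st[st$construct == "donor_alone", ],
                         st[st$construct == "null", ], "static"))
  expect_lt(abs(ev$E_mean), 0.02)
  expect_lt(ev$Zprime_mean, -1)
})

test_that("acceptor drift degrades dynamic Z' relative to static Z'", {
  cfg <- synthetic_study_config(pair_name = "mTq2-YPet",
                                tau_donor_true = 4.04,
                                tau_donor_cell_sd = 0.08,
                                E_true = 0.33, E_cell_sd = 0.02,
                                lifetime_drift_per_min = 0.01,
                                measurement = "gaussian", rng_seed = 13)
  tc <- generate_timecourse(cfg)
  donor <- tc[tc$construct == "donor_alone", ]
  pair <- tc[tc$construct == "mTq2-YPet", ]
  zs <- evaluate_assay(donor, pair, "static")$Zprime_mean
  zd <- evaluate_assay(donor, pair, "dynamic")$Zprime_mean
  expect_lt(zd, zs)
})

test_that("days lacking one arm are skipped; none usable is an error", {
  cfg <- synthetic_study_config(measurement = "gaussian", rng_seed = 3)
  st <- generate_study(cfg)
  donor <- st[st$construct == "donor_alone", ]
  pair <- st[st$construct == cfg$pair_name, ]
  expect_warning(ev <- evaluate_assay(donor[donor$day < 3, ], pair,
                                      "static"),
                 "skipped")
  expect_identical(ev$n_days, 2L)
  expect_error(suppressWarnings(
    evaluate_assay(donor[donor$day == 1, ], pair[pair$day == 2, ],
                   "static")),
    "no day")
})

test_that("cross-platform concordance is the perpendicular distance to the identity line", {
  expect_equal(concordance(0.5, 0.5)$distance, 0)
  expect_equal(concordance(0.6, 0.4)$distance, 0.1414, tolerance = 1e-3)
  # adding a common offset to both platforms leaves ranking unchanged
  z_fd <- c(0.7, 0.2, -0.5); z_td <- c(0.6, 0.4, -0.1)
  d0 <- mapply(function(a, b) concordance(a, b)$distance, z_fd, z_td)
  d1 <- mapply(function(a, b) concordance(a, b)$distance,
               z_fd + 0.3, z_td + 0.3)
  expect_identical(order(d0), order(d1))
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("lifetime sensitivity per efficiency point is 10 ps per ns of donor lifetime", {
  expect_equal(sensitivity_ps_per_percent(4.0), 40)
  expect_equal(sensitivity_ps_per_percent(2.4), 24)
  expect_equal(sensitivity_ps_per_percent(1.0), 10)
  expect_error(sensitivity_ps_per_percent(0), "positive")
})

make_stim_data <- function(E_step, n_cells = 30, tau_D = 4.0, seed = 55) {
  set.seed(seed)
  tps <- -2:2
  rows <- lapply(seq_len(n_cells), function(i) {
    E <- ifelse(tps > 0, E_step, 0)
    data.frame(cell_id = paste0("c", i), day = 1, timepoint = tps,
               lifetime = tau_D * (1 - E) + stats::rnorm(length(tps), 0, 0.03))
  })
  do.call(rbind, rows)
}

test_that("stimulation response detects a real efficiency step and not a null", {
  ctrl <- make_stim_data(0, seed = 56)
  # null sensor: no significant post-stimulation change
  null_res <- stimulation_response(make_stim_data(0), ctrl)
  expect_true(all(abs(null_res$delta_tau_mean) < 0.05))
  expect_true(all(null_res$stars[null_res$timepoint > 0] == ""))
  # a 5% efficiency step shifts lifetime by about -0.05 * 4.0 = -0.20 ns
  step_res <- stimulation_response(make_stim_data(0.05), ctrl)
  post <- step_res[step_res$timepoint > 0, ]
  for (i in seq_len(nrow(post))) {
    se <- post$delta_tau_sd[i] / sqrt(post$n_cells[i])
    expect_lt(abs(post$delta_tau_mean[i] - (-0.20)), 3 * se + 0.02)
  }
  expect_true(all(post$p_value < 0.005))
  expect_true(all(post$stars == "***"))
  # missing t = 0 is an error
  tc <- make_stim_data(0.05)
  expect_error(stimulation_response(tc[tc$timepoint != 0, ], ctrl),
               "t = 0")
})
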