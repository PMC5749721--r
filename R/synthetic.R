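#' Configuration for a synthetic FLIM-FRET study
#'
#' Describes a multi-day per-cell study with the structure the evaluation
#' pipeline assumes: `days` experimental days (each day one repeat),
#' `dishes_per_day` dishes, 10-20 cells per dish, a donor-alone arm and a
#' donor-acceptor pair arm.  Per-cell true donor lifetimes are
#' Normal(`tau_donor_true`, `tau_donor_cell_sd`); per-cell true FRET
#' efficiencies are Normal(`E_true`, `E_cell_sd`), optionally with a
#' maturation-failure subpopulation at E near 0 (`E_bimodal_fraction`)
#' emulating heterogeneous, poorly-performing acceptors.  Time-course
#' behaviour is controlled by an intensity photobleaching rate and an
#' upward lifetime drift of the pair arm (acceptor photodamage reduces
#' energy transfer over the acquisition).
#'
#' @param pair_name Label for the donor-acceptor construct.
#' @param platform `"FD"` (frequency domain) or `"TD"` (time domain).
#' @param days,dishes_per_day,cells_per_dish Study design (defaults 3, 3,
#'   15).
#' @param tau_donor_true,tau_donor_cell_sd True donor lifetime mean/SD, ns.
#' @param E_true,E_cell_sd True FRET efficiency mean/SD (fractions).
#' @param E_bimodal_fraction Fraction of pair cells with E ~ 0 (default 0;
#'   0.5 emulates a heterogeneous acceptor).
#' @param lifetime_drift_per_min Fractional upward drift of the pair-arm
#'   lifetime per minute (default 0).
#' @param intensity_bleach_rate_per_min Exponential intensity bleach rate
#'   per minute (default 0).
#' @param photon_budget Photons per measurement (default 1e6).
#' @param measurement `"full"` routes observed lifetimes through the
#'   actual frequency-/time-domain estimation code, including reference
#'   calibration against simulated instrument offsets, so estimator biases
#'   are exercised end to end; `"gaussian"` is a fast shortcut that adds
#'   Normal(0, `shortcut_sd`) ns directly to the truth.
#' @param shortcut_sd Measurement noise SD for the shortcut mode, ns.
#' @param rng_seed Integer seed; generated tables are byte-identical for
#'   identical configurations and seeds.
#' @return List of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(pair_name = "pair",
                                   platform = c("FD", "TD"),
                                   days = 3L, dishes_per_day = 3L,
                                   cells_per_dish = 15L,
                                   tau_donor_true = 3.12,
                                   tau_donor_cell_sd = 0.05,
                                   E_true = 0.241, E_cell_sd = 0.02,
                                   E_bimodal_fraction = 0,
                                   lifetime_drift_per_min = 0,
                                   intensity_bleach_rate_per_min = 0,
                                   photon_budget = 1e6,
                                   measurement = c("full", "gaussian"),
                                   shortcut_sd = 0.01,
                                   rng_seed = 1L) {
  platform <- match.arg(platform)
  measurement <- match.arg(measurement)
  stopifnot(days >= 1, dishes_per_day >= 1,
            cells_per_dish >= 1,
            tau_donor_true > 0, tau_donor_cell_sd >= 0,
            E_true >= 0, E_true < 1, E_cell_sd >= 0,
            E_bimodal_fraction >= 0, E_bimodal_fraction <= 1,
            lifetime_drift_per_min >= 0,
            intensity_bleach_rate_per_min >= 0,
            photon_budget > 0, shortcut_sd >= 0)
  structure(as.list(environment()), class = "synthetic_study_config")
}

# simulated instrument offsets for the FD path; removed by calibration
.FD_INSTRUMENT <- list(phase_offset = 0.3, gain = 0.8)

# measure one true lifetime through the configured platform path;
# reference is a pre-made noisy raw reference measurement (FD only)
.measure_lifetime <- function(tau_true, config, settings, raw_ref) {
  if (config$measurement == "gaussian")
    return(tau_true + stats::rnorm(1, 0, config$shortcut_sd))
  if (config$platform == "FD") {
    noisy <- simulate_fd_measurement(list(c(1, tau_true)), settings$omega,
                                     config$photon_budget)
    raw <- .fd_measurement(noisy$phase_phi + .FD_INSTRUMENT$phase_offset,
                           noisy$modulation_m * .FD_INSTRUMENT$gain)
    cal <- calibrate_reference(raw, raw_ref, settings)
    lifetime_from_phase(cal$phase_phi, settings$omega)
  } else {
    hist <- simulate_decay(list(c(1, tau_true)), config$photon_budget)
    fit_monoexp(hist)$taus
  }
}

# one noisy raw reference measurement under the same instrument offsets
.measure_reference <- function(config, settings) {
  noisy <- simulate_fd_measurement(list(c(1, settings$reference_tau)),
                                   settings$omega, config$photon_budget)
  .fd_measurement(noisy$phase_phi + .FD_INSTRUMENT$phase_offset,
                  noisy$modulation_m * .FD_INSTRUMENT$gain)
}

.draw_true_E <- function(n, config) {
  E <- stats::rnorm(n, config$E_true, config$E_cell_sd)
  if (config$E_bimodal_fraction > 0) {
    dud <- stats::runif(n) < config$E_bimodal_fraction
    E[dud] <- abs(stats::rnorm(sum(dud), 0, 0.01))
  }
  pmin(pmax(E, -0.2), 0.95)
}

#' Generate a synthetic single-timepoint study
#'
#' Produces the per-cell measurement table for a full multi-day study with
#' a donor-alone arm and a pair arm, all at timepoint 0.  Observed
#' lifetimes are produced by the platform measurement path selected in the
#' configuration; intensities get a multiplicative lognormal cell-to-cell
#' spread.
#'
#' @param config A `synthetic_study_config`.
#' @return Data frame with columns `cell_id`, `dish_id`, `day`, `platform`,
#'   `construct`, `timepoint`, `intensity`, `lifetime`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$rng_seed)
  settings <- .fd_settings_for(config)
  rows <- list()
  for (day in seq_len(config$days)) {
    raw_ref <- if (config$platform == "FD" && config$measurement == "full")
      .measure_reference(config, settings) else NULL
    for (dish in seq_len(config$dishes_per_day)) {
      for (arm in c("donor_alone", "pair")) {
        n <- config$cells_per_dish
        tau_d <- stats::rnorm(n, config$tau_donor_true,
                              config$tau_donor_cell_sd)
        E <- if (arm == "pair") .draw_true_E(n, config) else rep(0, n)
        tau_true <- tau_d * (1 - E)
        lifetime <- vapply(tau_true, .measure_lifetime, numeric(1),
                           config = config, settings = settings,
                           raw_ref = raw_ref)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = sprintf("%s_d%d_dish%d_c%d", arm, day, dish, seq_len(n)),
          dish_id = sprintf("d%d_dish%d", day, dish),
          day = day, platform = config$platform,
          construct = if (arm == "pair") config$pair_name else "donor_alone",
          timepoint = 0,
          intensity = stats::rlnorm(n, log(1000), 0.4),
          lifetime = lifetime)
      }
    }
  }
  do.call(rbind, rows)
}

.fd_settings_for <- function(config) {
  # fluorescein reference for the cyan band, erythrosin B for green; the
  # donor lifetime is the only cue available, so long-lifetime (cyan-like)
  # donors get fluorescein
  if (config$tau_donor_true >= 3.5) fd_settings(reference_name = "fluorescein")
  else fd_settings(reference_name = "erythrosinB")
}

#' Generate a synthetic time-course study
#'
#' As [generate_study()], but every cell is measured at each timepoint
#' (default every minute from 0 to 10).  Intensity decays exponentially at
#' the configured bleach rate with small multiplicative noise; the pair
#' arm's true lifetime drifts upward by `lifetime_drift_per_min` (fraction
#' of its t = 0 value) per minute, emulating acceptor photodamage, while
#' the donor-alone lifetime has no drift.
#'
#' @param config A `synthetic_study_config`.
#' @param timepoints Measurement times in minutes (default 0:10).
#' @return Data frame in the same layout as [generate_study()].
#' @export
generate_timecourse <- function(config, timepoints = 0:10) {
  stopifnot(inherits(config, "synthetic_study_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$rng_seed)
  settings <- .fd_settings_for(config)
  rows <- list()
  for (day in seq_len(config$days)) {
    raw_ref <- if (config$platform == "FD" && config$measurement == "full")
      .measure_reference(config, settings) else NULL
    for (dish in seq_len(config$dishes_per_day)) {
      for (arm in c("donor_alone", "pair")) {
        n <- config$cells_per_dish
        tau_d <- stats::rnorm(n, config$tau_donor_true,
                              config$tau_donor_cell_sd)
        E <- if (arm == "pair") .draw_true_E(n, config) else rep(0, n)
        tau0 <- tau_d * (1 - E)
        I0 <- stats::rlnorm(n, log(1000), 0.4)
        drift <- if (arm == "pair") config$lifetime_drift_per_min else 0
        for (t in timepoints) {
          tau_t <- pmin(tau0 * (1 + drift * t), tau_d)
          lifetime <- vapply(tau_t, .measure_lifetime, numeric(1),
                             config = config, settings = settings,
                             raw_ref = raw_ref)
          rows[[length(rows) + 1L]] <- data.frame(
            cell_id = sprintf("%s_d%d_dish%d_c%d", arm, day, dish,
                              seq_len(n)),
            dish_id = sprintf("d%d_dish%d", day, dish),
            day = day, platform = config$platform,
            construct = if (arm == "pair") config$pair_name
                        else "donor_alone",
            timepoint = t,
            intensity = I0 *
              exp(-config$intensity_bleach_rate_per_min * t) *
              stats::rlnorm(n, 0, 0.05),
            lifetime = lifetime)
        }
      }
    }
  }
  do.call(rbind, rows)
}
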