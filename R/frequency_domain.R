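#' Frequency-domain acquisition settings
#'
#' Homodyne frequency-domain FLIM settings: modulation frequency and the
#' reference fluorophore of known lifetime used to remove instrument phase
#' and gain offsets.  Fluorescein (tau = 4.000 ns) is the conventional
#' reference for the 445 nm excitation band and erythrosin B
#' (tau = 0.086 ns) for the 491 nm band.
#'
#' @param mod_frequency_f Modulation frequency in Hz (default 40 MHz).
#' @param reference_name Reference fluorophore identifier.
#' @param reference_tau Known reference lifetime, ns.
#' @return List of class `fd_settings` with `mod_frequency_f`, `omega`
#'   (rad/s), `reference_name`, `reference_tau`.
#' @export
fd_settings <- function(mod_frequency_f = 4.0e7,
                        reference_name = c("fluorescein", "erythrosinB",
                                           "custom"),
                        reference_tau = NULL) {
  reference_name <- match.arg(reference_name)
  if (mod_frequency_f <= 0) stop("modulation frequency must be positive")
  if (is.null(reference_tau))
    reference_tau <- switch(reference_name,
                            fluorescein = 4.000,
                            erythrosinB = 0.086,
                            stop("custom reference needs reference_tau"))
  if (reference_tau < 0) stop("reference_tau must be non-negative")
  structure(list(mod_frequency_f = mod_frequency_f,
                 omega = 2 * pi * mod_frequency_f,
                 reference_name = reference_name,
                 reference_tau = reference_tau),
            class = "fd_settings")
}

.fd_measurement <- function(phase, modulation, calibrated = FALSE) {
  if (phase < 0 || phase >= pi / 2)
    stop("phase must lie in [0, pi/2)")
  if (modulation <= 0) stop("modulation must be positive")
  if (modulation > 1 + 1e-6)
    stop("modulation exceeds 1 beyond noise tolerance")
  structure(list(phase_phi = phase, modulation_m = modulation,
                 calibrated = calibrated),
            class = "fd_measurement")
}

#' Homodyne frequency-domain response of a multi-exponential decay
#'
#' The forward model of a frequency-domain FLIM measurement: for a decay
#' with intensity fractions a_i and lifetimes tau_i, the complex response at
#' angular frequency omega is R = sum a_i / (1 + i * omega * tau_i); the
#' measured phase shift is phi = -Arg(R) and the demodulation m = |R|.  A
#' mono-exponential decay gives phi = atan(omega * tau) and
#' m = 1 / sqrt(1 + (omega * tau)^2).
#'
#' @param components Two-column matrix/data.frame or list of `c(a, tau)`
#'   pairs: intensity fractions (summing to 1) and lifetimes in ns.
#' @param omega Angular modulation frequency, rad/s.
#' @return An `fd_measurement` (calibrated, since this is the ideal
#'   instrument-free response).
#' @export
fd_response <- function(components, omega) {
  comp <- .as_components(components)
  if (abs(sum(comp$a) - 1) > 1e-9)
    stop("component fractions must sum to 1")
  if (any(comp$tau < 0)) stop("lifetimes must be non-negative")
  wt <- omega * comp$tau * 1e-9       # tau ns -> s
  R <- sum(comp$a / (1 + 1i * wt))
  .fd_measurement(phase = -Arg(R), modulation = Mod(R), calibrated = TRUE)
}

.as_components <- function(components) {
  if (is.list(components) && !is.data.frame(components) &&
      all(vapply(components, length, 1L) == 2L)) {
    m <- do.call(rbind, lapply(components, as.numeric))
  } else {
    m <- as.matrix(components)
  }
  if (ncol(m) != 2L) stop("components must be (fraction, tau) pairs")
  list(a = m[, 1], tau = m[, 2])
}

#' Phase lifetime
#'
#' Inverts the mono-exponential homodyne model for the phase channel:
#' tau_phi = tan(phi) / omega.  For heterogeneous decays this is a weighted
#' apparent lifetime that is strictly shorter than the modulation lifetime.
#'
#' @param phi Calibrated phase shift, rad, in [0, pi/2).
#' @param omega Angular modulation frequency, rad/s.
#' @return Phase lifetime in ns.
#' @export
lifetime_from_phase <- function(phi, omega) {
  if (any(phi < 0) || any(phi >= pi / 2))
    stop("phase must lie in [0, pi/2)")
  tan(phi) / omega * 1e9
}

#' Modulation lifetime
#'
#' tau_m = sqrt(1/m^2 - 1) / omega.  Values of m marginally above 1 (shot
#' noise) are clamped to 1 with a warning and return 0 ns.
#'
#' @param m Calibrated demodulation, in (0, 1].
#' @param omega Angular modulation frequency, rad/s.
#' @return Modulation lifetime in ns.
#' @export
lifetime_from_modulation <- function(m, omega) {
  if (any(m <= 0)) stop("modulation must be positive")
  if (any(m > 1 + 1e-6)) stop("modulation exceeds 1 beyond noise tolerance")
  if (any(m > 1)) {
    warning("modulation marginally above 1 clamped to 1")
    m <- pmin(m, 1)
  }
  sqrt(1 / m^2 - 1) / omega * 1e9
}

#' Calibrate a raw frequency-domain measurement against a reference
#'
#' Raw homodyne phase and modulation contain arbitrary instrument offsets.
#' Measuring a reference fluorophore of known lifetime under identical
#' settings removes them:
#' phi_cal = phi_sample - phi_ref + atan(omega * tau_ref) and
#' m_cal = (m_sample / m_ref) / sqrt(1 + (omega * tau_ref)^2).
#'
#' @param raw_sample,raw_reference Raw `fd_measurement` objects.
#' @param settings `fd_settings` carrying omega and the reference lifetime.
#' @return Calibrated `fd_measurement`.
#' @export
calibrate_reference <- function(raw_sample, raw_reference, settings) {
  stopifnot(inherits(settings, "fd_settings"))
  if (raw_reference$modulation_m <= 0)
    stop("reference modulation must be positive")
  wt_ref <- settings$omega * settings$reference_tau * 1e-9
  phi <- raw_sample$phase_phi - raw_reference$phase_phi + atan(wt_ref)
  m <- raw_sample$modulation_m / raw_reference$modulation_m /
    sqrt(1 + wt_ref^2)
  if (phi < 0) {
    if (phi < -1e-6)
      warning("calibrated phase negative beyond tolerance; clamped to 0")
    phi <- 0
  }
  if (m > 1 && m <= 1 + 1e-6) m <- 1
  .fd_measurement(phase = phi, modulation = m, calibrated = TRUE)
}

#' Phasor coordinates of a frequency-domain measurement
#'
#' Maps a calibrated measurement to the phasor plane:
#' g = m cos(phi), s = m sin(phi).  A 0 ns lifetime maps to (1, 0) and an
#' infinite lifetime to the origin; every noiseless mono-exponential decay
#' falls on the universal semicircle of radius 1/2 centred at (1/2, 0)
#' (often loosely called the "unit circle"), and any mixture of lifetimes
#' falls strictly inside it.
#'
#' @param meas A calibrated `fd_measurement`.
#' @return List of class `phasor_point` with elements `g` and `s`.
#' @export
phasor_coordinates <- function(meas) {
  if (!isTRUE(meas$calibrated))
    warning("phasor computed from uncalibrated measurement")
  structure(list(g = meas$modulation_m * cos(meas$phase_phi),
                 s = meas$modulation_m * sin(meas$phase_phi)),
            class = "phasor_point")
}

#' Simulate a noisy frequency-domain measurement
#'
#' Evaluates [fd_response()] and perturbs phase and modulation with
#' independent Gaussian shot noise whose standard deviation scales as
#' 1/sqrt(photons): sd(phi) = 1/sqrt(N), sd(m) = m/sqrt(N).  An infinite
#' photon budget reproduces the noiseless response exactly.
#'
#' @param true_components Decay components as in [fd_response()].
#' @param omega Angular modulation frequency, rad/s.
#' @param photon_budget Expected number of detected photons (> 0; may be
#'   `Inf`).
#' @param rng_seed Optional integer seed; when supplied the draw is
#'   deterministic and the caller's RNG state is left untouched.
#' @return An `fd_measurement` (calibrated = TRUE: noise is applied to the
#'   ideal instrument-free response).
#' @export
simulate_fd_measurement <- function(true_components, omega, photon_budget,
                                    rng_seed = NULL) {
  if (photon_budget <= 0) stop("photon_budget must be positive")
  ideal <- fd_response(true_components, omega)
  if (!is.finite(photon_budget)) return(ideal)
  if (!is.null(rng_seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(rng_seed)
  }
  sdv <- 1 / sqrt(photon_budget)
  phi <- ideal$phase_phi + stats::rnorm(1, 0, sdv)
  m <- ideal$modulation_m * (1 + stats::rnorm(1, 0, sdv))
  phi <- min(max(phi, 0), pi / 2 - 1e-12)
  m <- min(max(m, 1e-12), 1)
  .fd_measurement(phase = phi, modulation = m, calibrated = TRUE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
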