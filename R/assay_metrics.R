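#' FRET efficiency from donor lifetimes
#'
#' E = 1 - tau_pair / tau_donor, where tau_donor is the donor-alone
#' lifetime and tau_pair the donor lifetime in the presence of the
#' acceptor.  Noise can push tau_pair above tau_donor; the resulting small
#' negative efficiency is returned with a warning rather than clipped, so
#' downstream distributions stay honest.
#'
#' @param tau_donor Donor-alone lifetime, ns (> 0).
#' @param tau_pair Donor lifetime with acceptor, ns.
#' @return Efficiency as a fraction (may be slightly negative).
#' @export
efficiency_from_lifetimes <- function(tau_donor, tau_pair) {
  if (any(tau_donor <= 0)) stop("tau_donor must be positive")
  E <- 1 - tau_pair / tau_donor
  if (any(E < 0))
    warning("pair lifetime exceeds donor lifetime: negative efficiency (noise)")
  E
}

#' Z'-factor assay-quality statistic
#'
#' Z' = 1 - 3 * (sigma_max + sigma_min) / |mu_max - mu_min|, the screening
#' statistic comparing the separation of the maximum-signal population
#' (here, donor-alone lifetimes) and the minimum-signal population (donor
#' lifetimes in the FRET pair) to their spreads.  Z' is at most 1 (reached
#' only with zero variance); values above 0.5 indicate a good assay, and
#' negative values an assay whose readout shift is small relative to its
#' noise.
#'
#' @param mu_max,sigma_max Mean and SD of the maximum-signal population.
#' @param mu_min,sigma_min Mean and SD of the minimum-signal population.
#' @return The Z'-factor (dimensionless, <= 1).
#' @export
z_factor <- function(mu_max, sigma_max, mu_min, sigma_min) {
  if (any(sigma_max < 0) || any(sigma_min < 0))
    stop("standard deviations must be non-negative")
  if (any(mu_max == mu_min))
    stop("undefined separation: mu_max equals mu_min")
  1 - 3 * (sigma_max + sigma_min) / abs(mu_max - mu_min)
}

.check_cells <- function(df, what = "cell measurements") {
  req <- c("cell_id", "day", "timepoint", "lifetime")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  df
}

#' Evaluate the assay potential of a FRET pair
#'
#' Implements the day-repeat evaluation design: within each experimental
#' day, the mean and standard deviation (n-1 denominator, across cells) of
#' the donor-alone lifetimes form the maximum signal and those of the
#' donor-acceptor pair lifetimes the minimum signal; Z' follows from
#' [z_factor()] and the FRET efficiency from the day-matched donor mean,
#' E = 1 - mean(pair) / mean(donor).  Each day is one repeat; the function
#' returns the across-day mean and SD of both statistics.
#'
#' In `"static"` mode only timepoint-0 records are used; in `"dynamic"`
#' mode all timepoints of all cells within a day are pooled before the
#' mean/SD are taken, so temporal drift inflates sigma and is penalised in
#' Z'.  With `per_cell_average = TRUE` each cell's time course is averaged
#' first.
#'
#' @param donor_cells,pair_cells Data frames of per-cell measurements with
#'   columns `cell_id`, `day`, `timepoint`, `lifetime` (see
#'   [read_cell_measurements()]).
#' @param mode `"static"` or `"dynamic"`.
#' @param per_cell_average In dynamic mode, average each cell's trace
#'   before pooling (default `FALSE`: pool all timepoints).
#' @return Object of class `assay_evaluation`: `E_mean`, `E_sd`,
#'   `Zprime_mean`, `Zprime_sd`, `n_days`, `mode`, `per_day` (data frame of
#'   per-day statistics).
#' @export
evaluate_assay <- function(donor_cells, pair_cells,
                           mode = c("static", "dynamic"),
                           per_cell_average = FALSE) {
  mode <- match.arg(mode)
  donor_cells <- .check_cells(donor_cells, "donor_cells")
  pair_cells <- .check_cells(pair_cells, "pair_cells")
  if (mode == "static") {
    donor_cells <- donor_cells[donor_cells$timepoint == 0, , drop = FALSE]
    pair_cells <- pair_cells[pair_cells$timepoint == 0, , drop = FALSE]
  } else if (per_cell_average) {
    donor_cells <- .average_per_cell(donor_cells)
    pair_cells <- .average_per_cell(pair_cells)
  }
  days <- intersect(unique(donor_cells$day), unique(pair_cells$day))
  skipped <- setdiff(union(unique(donor_cells$day),
                           unique(pair_cells$day)), days)
  if (length(skipped))
    warning(sprintf("day(s) without both arms skipped: %s",
                    paste(skipped, collapse = ", ")))
  if (!length(days)) stop("no day with both donor and pair measurements")
  per_day <- do.call(rbind, lapply(days, function(d) {
    x <- donor_cells$lifetime[donor_cells$day == d]
    y <- pair_cells$lifetime[pair_cells$day == d]
    data.frame(day = d,
               mu_max = mean(x), sigma_max = stats::sd(x),
               mu_min = mean(y), sigma_min = stats::sd(y),
               Zprime = z_factor(mean(x), stats::sd(x),
                                 mean(y), stats::sd(y)),
               E = 1 - mean(y) / mean(x))
  }))
  if (any(per_day$E < 0))
    warning("negative day-level FRET efficiency retained (noise)")
  structure(list(mode = mode,
                 E_mean = mean(per_day$E),
                 E_sd = if (nrow(per_day) > 1) stats::sd(per_day$E) else NA_real_,
                 Zprime_mean = mean(per_day$Zprime),
                 Zprime_sd = if (nrow(per_day) > 1) stats::sd(per_day$Zprime) else NA_real_,
                 n_days = nrow(per_day),
                 per_day = per_day),
            class = "assay_evaluation")
}

.average_per_cell <- function(df) {
  agg <- stats::aggregate(lifetime ~ cell_id + day, data = df, FUN = mean)
  agg$timepoint <- 0
  agg
}

#' @export
print.assay_evaluation <- function(x, ...) {
  cat(sprintf("Assay evaluation (%s, %d day repeats)\n", x$mode, x$n_days))
  cat(sprintf("  FRET efficiency: %.1f%% +/- %.1f%%\n",
              100 * x$E_mean, 100 * x$E_sd))
  cat(sprintf("  Z'-factor:       %.3f +/- %.3f\n",
              x$Zprime_mean, x$Zprime_sd))
  invisible(x)
}

#' Cross-platform concordance of Z'-factors
#'
#' Pairs evaluated on two FLIM platforms that behave identically fall on
#' the identity line of a Z'(platform 1) versus Z'(platform 2) plot; the
#' perpendicular distance |Z'_1 - Z'_2| / sqrt(2) quantifies the departure.
#'
#' @param eval_fd,eval_td `assay_evaluation` objects for the same pair on
#'   the two platforms, or bare Z' values.
#' @return List with `Zprime_fd`, `Zprime_td` and `distance`.
#' @export
concordance <- function(eval_fd, eval_td) {
  z1 <- if (inherits(eval_fd, "assay_evaluation")) eval_fd$Zprime_mean else eval_fd
  z2 <- if (inherits(eval_td, "assay_evaluation")) eval_td$Zprime_mean else eval_td
  list(Zprime_fd = z1, Zprime_td = z2,
       distance = abs(z1 - z2) / sqrt(2))
}

#' Lifetime sensitivity per FRET-efficiency point
#'
#' Since the lifetime shift is tau_D * E, a one-percentage-point change in
#' efficiency moves the measured lifetime by tau_D / 100 — i.e.
#' 10 * tau_D picoseconds.  A 4.0 ns donor therefore yields 40 ps per %E,
#' twice the leverage of a 2.0 ns donor — the case for long-lifetime
#' donors in a nutshell.
#'
#' @param tau_donor Donor lifetime, ns.
#' @return Sensitivity in ps per percentage point of FRET efficiency.
#' @export
sensitivity_ps_per_percent <- function(tau_donor) {
  if (any(tau_donor <= 0)) stop("tau_donor must be positive")
  tau_donor * 1000 / 100
}

#' Stimulation-response analysis of a biosensor time course
#'
#' For a time course bracketing a stimulation at t = 0 (timepoints in
#' minutes, e.g. -2, -1, 0, +1, +2), computes per-timepoint lifetime
#' changes relative to each cell's t = 0 value, FRET efficiencies against
#' the time-matched mean of donor-alone control traces acquired under the
#' same protocol, and the significance of post- versus pre-stimulation
#' lifetime changes by a two-sided rank-sum (Wilcoxon) test with the usual
#' star convention (* p < 0.05, ** p < 0.01, *** p < 0.005).
#'
#' @param timecourse Per-cell sensor measurements (`cell_id`, `day`,
#'   `timepoint`, `lifetime`).
#' @param donor_controls Donor-alone control measurements on the same
#'   timepoint grid.
#' @return Data frame with one row per timepoint: `timepoint`,
#'   `delta_tau_mean`, `delta_tau_sd`, `E_mean`, `n_cells`, `p_value`
#'   (post-stimulation rows only), `stars`.
#' @export
stimulation_response <- function(timecourse, donor_controls) {
  timecourse <- .check_cells(timecourse, "timecourse")
  donor_controls <- .check_cells(donor_controls, "donor_controls")
  if (!any(timecourse$timepoint == 0))
    stop("time course lacks the t = 0 stimulation point")
  tps <- sort(unique(timecourse$timepoint))
  base <- timecourse[timecourse$timepoint == 0,
                     c("cell_id", "day", "lifetime")]
  names(base)[3] <- "lifetime0"
  tc <- merge(timecourse, base, by = c("cell_id", "day"))
  tc$delta_tau <- tc$lifetime - tc$lifetime0
  ctrl_mean <- stats::aggregate(lifetime ~ timepoint, data = donor_controls,
                                FUN = mean)
  pre <- tc$delta_tau[tc$timepoint < 0]
  out <- do.call(rbind, lapply(tps, function(t) {
    d <- tc$delta_tau[tc$timepoint == t]
    ctrl <- ctrl_mean$lifetime[ctrl_mean$timepoint == t]
    E <- if (length(ctrl))
      mean(1 - tc$lifetime[tc$timepoint == t] / ctrl) else NA_real_
    p <- if (t > 0 && length(pre))
      suppressWarnings(stats::wilcox.test(d, pre)$p.value) else NA_real_
    data.frame(timepoint = t,
               delta_tau_mean = mean(d), delta_tau_sd = stats::sd(d),
               E_mean = E, n_cells = length(d), p_value = p,
               stars = .p_stars(p))
  }))
  rownames(out) <- NULL
  out
}

.p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.005) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
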