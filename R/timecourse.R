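#' Normalise per-cell time courses to the day mean at t = 0
#'
#' Each value is divided by the across-cell mean of the t = 0 values of its
#' experimental day, so traces from days with different absolute scales
#' become comparable and the day-average trace starts at 1 by construction.
#' The input is expected to hold one construct/platform combination;
#' normalisation groups by `day` only.
#'
#' @param cells Per-cell measurements with columns `cell_id`, `day`,
#'   `timepoint` and the measured quantity.
#' @param quantity Which column to normalise: `"lifetime"` or
#'   `"intensity"`.
#' @return Data frame with columns `cell_id`, `day`, `timepoint`, `value`
#'   (normalised).
#' @export
normalize_traces <- function(cells, quantity = c("lifetime", "intensity")) {
  quantity <- match.arg(quantity)
  req <- c("cell_id", "day", "timepoint", quantity)
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  out <- NULL
  for (d in unique(cells$day)) {
    sub <- cells[cells$day == d, , drop = FALSE]
    t0 <- sub[[quantity]][sub$timepoint == 0]
    if (!length(t0)) {
      warning(sprintf("day %s has no t = 0 records and was excluded", d))
      next
    }
    out <- rbind(out, data.frame(cell_id = sub$cell_id, day = d,
                                 timepoint = sub$timepoint,
                                 value = sub[[quantity]] / mean(t0)))
  }
  if (is.null(out)) stop("no usable day in input")
  out
}

#' Linear drift of the mean normalised trace
#'
#' Ordinary least-squares straight line through the across-cell mean of
#' normalised values at each timepoint.  The gradient (fractional change
#' per minute) is the photostability summary: near-zero for stable
#' constructs, negative under bleaching, positive for lifetime drift from
#' acceptor photodamage.
#'
#' @param traces Output of [normalize_traces()] (columns `timepoint`,
#'   `value`).
#' @return List with `slope` (per minute), `se`, `intercept`.
#' @export
drift_slope <- function(traces) {
  mean_trace <- stats::aggregate(value ~ timepoint, data = traces,
                                 FUN = mean)
  if (nrow(mean_trace) < 3L)
    stop("drift fit needs at least 3 timepoints")
  fit <- stats::lm(value ~ timepoint, data = mean_trace)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["timepoint", "Estimate"]),
       se = unname(cf["timepoint", "Std. Error"]),
       intercept = unname(cf["(Intercept)", "Estimate"]))
}

#' Summary of per-cell endpoint changes over a time course
#'
#' For each cell the difference between its value at the last timepoint
#' (default 10 min) and at t = 0 is taken; the distribution is summarised
#' by its mean, median and the 10th/25th/75th/90th percentiles (linear
#' interpolation between closest ranks), plus the SD of the full trace set
#' as an overall variability marker.
#'
#' @param traces Output of [normalize_traces()].
#' @param t_end Endpoint timepoint (default 10).
#' @return List with `changes` (per-cell vector), `mean`, `median`, `p10`,
#'   `p25`, `p75`, `p90`, `total_sd`.
#' @export
endpoint_change_summary <- function(traces, t_end = 10) {
  a <- traces[traces$timepoint == 0, c("cell_id", "day", "value")]
  b <- traces[traces$timepoint == t_end, c("cell_id", "day", "value")]
  if (!nrow(a) || !nrow(b))
    stop("traces must contain both t = 0 and the endpoint")
  m <- merge(a, b, by = c("cell_id", "day"), suffixes = c("0", "1"))
  ch <- m$value1 - m$value0
  q <- stats::quantile(ch, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  list(changes = ch, mean = mean(ch), median = stats::median(ch),
       p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4],
       total_sd = stats::sd(traces$value))
}

#' Correlation between lifetime and intensity variability
#'
#' Spearman rank correlation (two-sided) between per-construct percentage
#' standard deviations of lifetime and of intensity, testing whether
#' lifetime noise merely tracks expression-level noise.
#'
#' @param sd_lifetime,sd_intensity Paired percentage-SD vectors, one entry
#'   per construct.
#' @return List with `rho` and `p_value`.
#' @export
variability_correlation <- function(sd_lifetime, sd_intensity) {
  if (length(sd_lifetime) != length(sd_intensity))
    stop("inputs must be paired")
  if (length(sd_lifetime) < 4L)
    stop("need at least 4 paired observations")
  if (stats::sd(sd_lifetime) == 0 || stats::sd(sd_intensity) == 0)
    stop("constant input vector: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(sd_lifetime, sd_intensity, method = "spearman",
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Through-origin regression of measured on predicted FRET efficiencies
#'
#' Fits y = b x through the origin: b = sum(xy) / sum(x^2), with R^2
#' defined on the no-intercept model as 1 - sum((y - b x)^2) / sum(y^2),
#' and a 95% confidence interval for b from the through-origin standard
#' error.  Pairs known to behave anomalously can be excluded explicitly
#' (never automatically) via `exclude`.
#'
#' @param predicted_E Named vector of predicted efficiencies, one per pair.
#' @param measured_E Named vector of measured efficiencies (same names).
#' @param exclude Character vector of pair names to drop before fitting.
#' @return List with `gradient`, `r_squared`, `se`, `ci95` (length-2),
#'   `n_pairs`.
#' @export
predicted_vs_measured_fit <- function(predicted_E, measured_E,
                                      exclude = character()) {
  if (!is.null(names(predicted_E)) && !is.null(names(measured_E)))
    measured_E <- measured_E[names(predicted_E)]
  if (length(predicted_E) != length(measured_E))
    stop("predicted and measured vectors must be paired")
  if (length(exclude)) {
    keep <- !(names(predicted_E) %in% exclude)
    predicted_E <- predicted_E[keep]
    measured_E <- measured_E[keep]
  }
  n <- length(predicted_E)
  if (n < 3L) stop("need at least 3 pairs after exclusion")
  if (all(predicted_E == 0)) stop("all-zero predictor")
  x <- as.numeric(predicted_E); y <- as.numeric(measured_E)
  b <- sum(x * y) / sum(x^2)
  resid <- y - b * x
  se <- sqrt(sum(resid^2) / (n - 1) / sum(x^2))
  tq <- stats::qt(0.975, df = n - 1)
  list(gradient = b,
       r_squared = 1 - sum(resid^2) / sum(y^2),
       se = se,
       ci95 = c(b - tq * se, b + tq * se),
       n_pairs = n)
}
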