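make_traces <- function(n_cells = 8, days = 2, scale = c(1, 1),
                        slope = 0, noise = 0, seed = 71) {
  set.seed(seed)
  rows <- list()
  for (d in seq_len(days)) {
    for (i in seq_len(n_cells)) {
      t <- 0:10
      v <- scale[d] * (1 + slope * t) + stats::rnorm(11, 0, noise)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sprintf("d%d_c%d", d, i), day = d, timepoint = t,
        lifetime = v, intensity = v * 500)
    }
  }
  do.call(rbind, rows)
}

test_that("trace normalisation anchors each day's t = 0 mean at 1", {
  cells <- make_traces(scale = c(2.5, 4.0))
  norm <- normalize_traces(cells)
  for (d in 1:2)
    expect_equal(mean(norm$value[norm$day == d & norm$timepoint == 0]), 1,
                 tolerance = 1e-12)
  # days with different absolute scales but identical shapes normalise
  # identically
  expect_equal(norm$value[norm$day == 1], norm$value[norm$day == 2],
               tolerance = 1e-12)
  # idempotent on already-normalised data
  renorm <- normalize_traces(
    data.frame(cell_id = norm$cell_id, day = norm$day,
               timepoint = norm$timepoint, lifetime = norm$value))
  expect_equal(renorm$value, norm$value, tolerance = 1e-12)
  # a day with no t = 0 record is excluded with a warning
  broken <- cells[!(cells$day == 2 & cells$timepoint == 0), ]
  expect_warning(n2 <- normalize_traces(broken), "excluded")
  expect_identical(sort(unique(n2$day)), 1L)
})

test_that("drift slope recovers exact lines and linearised bleach rates", {
  flat <- normalize_traces(make_traces(slope = 0))
  fit <- suppressWarnings(drift_slope(flat))  # lm warns on an exact fit
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  lin <- normalize_traces(make_traces(slope = -0.02))
  fit2 <- suppressWarnings(drift_slope(lin))
  expect_equal(fit2$slope, -0.02, tolerance = 1e-12)
  expect_equal(fit2$se, 0, tolerance = 1e-9)
  # gentle exponential bleach exp(-0.01 t) looks linear over 10 min with
  # slope near -0.01 (small rate x duration)
  cells <- make_traces()
  cells$lifetime <- exp(-0.01 * cells$timepoint)
  expfit <- drift_slope(normalize_traces(cells))
  expect_equal(expfit$slope, -0.01, tolerance = 0.1)
  expect_error(drift_slope(flat[flat$timepoint < 2, ]), "3 timepoints")
})

test_that("drift of driftless noisy traces is statistically zero", {
  set.seed(83)
  slopes <- replicate(200, {
    cells <- make_traces(n_cells = 10, days = 1, noise = 0.02,
                         seed = sample.int(1e6, 1))
    fit <- drift_slope(normalize_traces(cells))
    fit$slope / fit$se
  })
  # standardised slopes should look standard-normal: mean within 3 SE
  expect_lt(abs(mean(slopes)), 3 / sqrt(length(slopes)) * stats::sd(slopes))
})

test_that("endpoint-change percentiles equal a sort-based oracle", {
  set.seed(91)
  cells <- make_traces(n_cells = 40, days = 1, noise = 0.05)
  traces <- normalize_traces(cells)
  summ <- endpoint_change_summary(traces)
  # brute-force oracle: per-cell differences, sorted, interpolated ranks
  v0 <- traces[traces$timepoint == 0, ]
  v1 <- traces[traces$timepoint == 10, ]
  mm <- merge(v0, v1, by = c("cell_id", "day"))
  ch <- sort(mm$value.y - mm$value.x)
  rank_quantile <- function(s, p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  expect_equal(summ$p10, rank_quantile(ch, 0.10), tolerance = 1e-12)
  expect_equal(summ$p25, rank_quantile(ch, 0.25), tolerance = 1e-12)
  expect_equal(summ$p75, rank_quantile(ch, 0.75), tolerance = 1e-12)
  expect_equal(summ$p90, rank_quantile(ch, 0.90), tolerance = 1e-12)
  expect_equal(summ$median, stats::median(ch))
  expect_true(summ$p10 <= summ$p25 && summ$p25 <= summ$median &&
                summ$median <= summ$p75 && summ$p75 <= summ$p90)
  # deterministic -10% bleach: every percentile at -0.10
  det <- make_traces(n_cells = 10, days = 1, slope = -0.01)
  dsum <- endpoint_change_summary(normalize_traces(det))
  expect_equal(unname(c(dsum$p10, dsum$p25, dsum$median, dsum$p75,
                        dsum$p90)),
               rep(-0.10, 5), tolerance = 1e-12)
})

test_that("variability correlation is a two-sided Spearman test with sane edge cases", {
  expect_equal(variability_correlation(1:6, c(2, 4, 5, 7, 8, 11))$rho, 1)
  expect_equal(variability_correlation(1:6, -(1:6))$rho, -1)
  expect_error(variability_correlation(rep(1, 6), 1:6), "constant")
  expect_error(variability_correlation(1:3, 1:3), "4 paired")
  # type-I error calibration on independent draws
  set.seed(97)
  rejections <- replicate(400, {
    variability_correlation(stats::rnorm(15), stats::rnorm(15))$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.035)
})

test_that("through-origin regression of measured on predicted efficiencies", {
  x <- c(a = 0.2, b = 0.3, c = 0.35, d = 0.25)
  fit <- predicted_vs_measured_fit(x, x)
  expect_equal(fit$gradient, 1)
  expect_equal(fit$r_squared, 1)
  half <- predicted_vs_measured_fit(x, 0.5 * x)
  expect_equal(half$gradient, 0.5, tolerance = 1e-12)
  # exclusion is explicit, by name
  x2 <- c(x, outlier = 0.4)
  y2 <- c(x, outlier = 0.05)
  fit2 <- predicted_vs_measured_fit(x2, y2, exclude = "outlier")
  expect_equal(fit2$gradient, 1)
  expect_identical(fit2$n_pairs, 4L)
  expect_error(predicted_vs_measured_fit(x[1:2], x[1:2]), "at least 3")
  expect_error(predicted_vs_measured_fit(0 * x, x), "all-zero")
})

test_that("benchmark measured efficiencies track 6 nm predictions with gradient near 0.96", {
  pairs <- flim_pair_table()
  meas <- flim_measured_assays()
  meas <- meas[meas$mode == "static", ]
  m <- merge(pairs, meas, by = "pair")
  pred6 <- 100 * efficiency_at_distance(m$r0_ref, 6)
  names(pred6) <- m$pair
  measured <- (m$E_pct_FD + m$E_pct_TD) / 2
  names(measured) <- m$pair
  fit <- predicted_vs_measured_fit(pred6, measured,
                                   exclude = c("Clv-mR2", "EGFP-mR2"))
  expect_equal(fit$gradient, 0.96, tolerance = 0.021)
  expect_gt(fit$r_squared, 0.98)
})
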