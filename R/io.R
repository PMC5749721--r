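#' Read a fluorophore property table
#'
#' Parses a comma-separated table of fluorophore photophysical constants
#' with required columns `name`, `ex`, `em`, `tau_ns`, `qy`, `eps_e3`
#' (peak excitation and emission wavelengths in nm, donor lifetime in ns,
#' quantum yield, and peak extinction coefficient in 10^3 M^-1 cm^-1;
#' lifetime/quantum yield may be empty for acceptor-only records, the
#' extinction coefficient for donor-only records).  Extra columns are kept
#' with a warning.
#'
#' @param path Path to the CSV file; defaults to the benchmark table of
#'   nine fluorescent proteins (four donors, five acceptors) bundled with
#'   the package.
#' @return Data frame of validated fluorophore records.
#' @export
read_fluorophore_table <- function(path = flim_extdata("fluorophores.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty fluorophore table")
  req <- c("name", "ex", "em", "tau_ns", "qy", "eps_e3")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(tab), c(req, "role"))
  if (length(extra))
    warning(sprintf("ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")))
  for (col in c("ex", "em", "tau_ns", "qy", "eps_e3")) {
    raw <- tab[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & trimws(as.character(raw)) != "" & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d", col, bad[1]))
    tab[[col]] <- num
  }
  if (any(!is.na(tab$qy) & (tab$qy <= 0 | tab$qy > 1)))
    stop("quantum yields must lie in (0, 1]")
  if (any(!is.na(tab$eps_e3) & tab$eps_e3 <= 0))
    stop("extinction coefficients must be positive")
  stokes <- !is.na(tab$ex) & !is.na(tab$em) & tab$em < tab$ex
  if (any(stokes))
    warning(sprintf("emission peak below excitation peak for: %s",
                    paste(tab$name[stokes], collapse = ", ")))
  tab
}

#' Path to a file bundled with the package
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
flim_extdata <- function(file) {
  p <- system.file("extdata", file, package = "flimpair", mustWork = TRUE)
  p
}

#' Bundled donor-acceptor pair benchmark table
#'
#' Ten fluorescent-protein FRET pairs (green donors Clover/EGFP with
#' mCherry/mRuby2; cyan donors mTFP1/mTurquoise2 with YPet/Venus/sREACh)
#' with the donor quantum yield, the spectral overlap integral J
#' (nm^4 M^-1 cm^-1) computed from published spectra, and the reference
#' Forster radius (nm) under the `table2_compat` orientation convention.
#'
#' @return Data frame with columns `pair`, `donor`, `acceptor`,
#'   `qy_donor`, `J`, `r0_ref`.
#' @export
flim_pair_table <- function() {
  utils::read.csv(flim_extdata("pair_benchmark.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled benchmark of measured assay performance
#'
#' Measured FRET efficiencies (percent) and Z'-factors for the ten
#' benchmark pairs on the frequency-domain (FD) and multiphoton
#' time-domain (TD) platforms, as mean +/- SD over three day-repeats, both
#' for single-timepoint (`static`) and 10-minute time-course (`dynamic`)
#' evaluation.
#'
#' @return Data frame keyed by `pair` and `mode`.
#' @export
flim_measured_assays <- function() {
  utils::read.csv(flim_extdata("measured_assay_benchmark.csv"),
                  stringsAsFactors = FALSE)
}

#' Read a per-cell measurement table
#'
#' Validates a CSV of per-cell FLIM measurements with required columns
#' `cell_id`, `dish_id`, `day`, `platform`, `construct`, `timepoint`,
#' `intensity`, `lifetime`.  Rows with a negative lifetime are dropped
#' with a warning; duplicated (cell, timepoint) combinations are an error.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_cell_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "dish_id", "day", "platform", "construct",
           "timepoint", "intensity", "lifetime")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  for (col in c("timepoint", "intensity", "lifetime")) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(num) && !anyNA(tab[[col]]))
      stop(sprintf("non-numeric value in column '%s'", col))
    tab[[col]] <- num
  }
  bad <- !is.na(tab$lifetime) & tab$lifetime <= 0
  if (any(bad)) {
    warning(sprintf("%d row(s) with non-positive lifetime dropped",
                    sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  key <- paste(tab$cell_id, tab$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (cell_id, timepoint) rows")
  tab
}

#' Write an evaluation report
#'
#' Writes a tidy CSV of assay evaluations plus a JSON sidecar embedding
#' provenance (seed, package version, timestamp-free config echo) so runs
#' are reproducible from the report alone.
#'
#' @param evaluations Named list of `assay_evaluation` objects (names are
#'   pair labels) or a pre-built data frame.
#' @param path Output CSV path; the JSON sidecar gets the same path with a
#'   `.json` extension.
#' @param seed Seed used for the run (recorded in the manifest).
#' @param config Optional list echoed into the manifest.
#' @return Invisibly, the tidy data frame written.
#' @export
write_report <- function(evaluations, path, seed = NA_integer_,
                         config = NULL) {
  if (is.data.frame(evaluations)) {
    tidy <- evaluations
  } else {
    tidy <- do.call(rbind, lapply(names(evaluations), function(nm) {
      e <- evaluations[[nm]]
      data.frame(pair = nm, mode = e$mode, n_days = e$n_days,
                 E_mean = e$E_mean, E_sd = e$E_sd,
                 Zprime_mean = e$Zprime_mean, Zprime_sd = e$Zprime_sd)
    }))
    if (is.null(tidy))
      tidy <- data.frame(pair = character(), mode = character(),
                         n_days = integer(), E_mean = numeric(),
                         E_sd = numeric(), Zprime_mean = numeric(),
                         Zprime_sd = numeric())
  }
  utils::write.csv(tidy, path, row.names = FALSE)
  manifest <- list(
    package = "flimpair",
    version = as.character(utils::packageVersion("flimpair")),
    seed = seed,
    config = config,
    columns = names(tidy),
    n_rows = nrow(tidy))
  jsonlite::write_json(manifest, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tidy)
}
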