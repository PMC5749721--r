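#' Construct a spectrum object
#'
#' A spectrum is a wavelength-gridded curve: either a donor emission spectrum
#' (arbitrary amplitude units, later normalised to unit area) or an acceptor
#' excitation spectrum expressed in molar extinction units (M^-1 cm^-1).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param values Non-negative amplitudes, one per wavelength.
#' @param kind `"emission"` or `"extinction"`.
#' @return An object of class `flim_spectrum`.
#' @export
flim_spectrum <- function(wavelengths, values,
                     kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have the same length")
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least 2 grid points")
  if (any(!is.finite(wavelengths)) || any(!is.finite(values)))
    stop("spectrum contains non-finite entries")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(values < 0))
    stop("spectrum values must be non-negative")
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "flim_spectrum")
}

#' @export
print.flim_spectrum <- function(x, ...) {
  cat(sprintf("<flim_spectrum: %s, %d points, %.0f-%.0f nm>\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# trapezoidal rule on an irregular grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Normalise an emission spectrum to unit area
#'
#' Rescales a donor emission spectrum so that its trapezoidal integral over
#' the wavelength grid equals 1, as required for the overlap integral.
#'
#' @param spec A `flim_spectrum` of kind `"emission"`.
#' @return The rescaled `flim_spectrum`.
#' @export
normalize_emission <- function(spec) {
  stopifnot(inherits(spec, "flim_spectrum"))
  if (spec$kind != "emission")
    stop("normalize_emission expects an emission spectrum")
  area <- .trapz(spec$wavelengths, spec$values)
  if (area <= 0)
    stop("degenerate spectrum: total area is zero")
  flim_spectrum(spec$wavelengths, spec$values / area, kind = "emission")
}

#' Spectral overlap integral J
#'
#' Computes J = integral of f_D(lambda) * eps_A(lambda) * lambda^4 over
#' wavelength, where f_D is the area-normalised donor emission spectrum and
#' eps_A the acceptor excitation spectrum in extinction units.  Both spectra
#' are resampled onto the union of their grids by linear interpolation, with
#' zero outside either support, and integrated trapezoidally.
#'
#' @param donor_em Donor emission `flim_spectrum` (normalised; spectra that
#'   do not integrate to 1 are normalised internally).
#' @param acceptor_ex Acceptor excitation `flim_spectrum` of kind
#'   `"extinction"`, values in M^-1 cm^-1.
#' @return Overlap integral J in nm^4 M^-1 cm^-1.
#' @export
overlap_integral <- function(donor_em, acceptor_ex) {
  stopifnot(inherits(donor_em, "flim_spectrum"),
            inherits(acceptor_ex, "flim_spectrum"))
  if (acceptor_ex$kind != "extinction")
    stop("acceptor spectrum must be of kind 'extinction'")
  donor_em <- normalize_emission(donor_em)
  lo <- max(min(donor_em$wavelengths), min(acceptor_ex$wavelengths))
  hi <- min(max(donor_em$wavelengths), max(acceptor_ex$wavelengths))
  if (lo >= hi) {
    warning("disjoint wavelength supports: J = 0")
    return(0)
  }
  grid <- sort(unique(c(donor_em$wavelengths, acceptor_ex$wavelengths)))
  grid <- grid[grid >= lo & grid <= hi]
  fd <- stats::approx(donor_em$wavelengths, donor_em$values, xout = grid,
                      yleft = 0, yright = 0)$y
  ea <- stats::approx(acceptor_ex$wavelengths, acceptor_ex$values,
                      xout = grid, yleft = 0, yright = 0)$y
  .trapz(grid, fd * ea * grid^4)
}

#' Parametric Gaussian stand-in spectrum
#'
#' Generates a Gaussian-shaped spectrum on a 1 nm grid spanning the peak
#' +/- 4 standard deviations.  Used by the synthetic-data layer in place of
#' measured fluorophore spectra.
#'
#' @param peak Peak wavelength, nm.
#' @param fwhm Full width at half maximum, nm.
#' @param kind `"emission"` or `"extinction"`.
#' @param peak_value Amplitude at the peak.  For extinction spectra set this
#'   to the molar extinction coefficient (M^-1 cm^-1); for emission spectra
#'   the scale is irrelevant after normalisation.
#' @param grid_step Grid spacing, nm (default 1).
#' @return A `flim_spectrum`.
#' @export
gaussian_spectrum <- function(peak, fwhm, kind = c("emission", "extinction"),
                              peak_value = 1, grid_step = 1) {
  kind <- match.arg(kind)
  if (fwhm <= 0) stop("fwhm must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / grid_step)         # grid lands on the peak
  wl <- peak + seq(-half, half) * grid_step
  vals <- peak_value * exp(-(wl - peak)^2 / (2 * sigma^2))
  flim_spectrum(wl, vals, kind = kind)
}

#' Read a two-column spectrum file
#'
#' Accepts delimited text with columns wavelength (nm) and value, header
#' optional, comma or whitespace separated (FPbase-style CSV exports work
#' as-is).
#'
#' @param path File path.
#' @param kind Spectrum kind, `"emission"` or `"extinction"`.
#' @param peak_eps For extinction spectra given on a normalised 0-1 scale,
#'   multiply by this peak extinction coefficient; `NULL` to use values
#'   verbatim.
#' @return A `flim_spectrum`.
#' @export
read_spectrum <- function(path, kind = c("emission", "extinction"),
                          peak_eps = NULL) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, if (sep == ",") "," else "[[:space:]]+")[[1]][1])))
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           strip.white = TRUE)
  if (ncol(tab) < 2L) stop("spectrum file needs two columns")
  vals <- as.numeric(tab[[2]])
  if (!is.null(peak_eps)) vals <- vals / max(vals) * peak_eps
  flim_spectrum(as.numeric(tab[[1]]), vals, kind = kind)
}
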