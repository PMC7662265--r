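# Circular dichroism: unit conversion, smoothing, spectral-shape
# classification, and the single-wavelength (222 nm) helix estimator.

#' Construct a CD spectrum
#'
#' @param wavelengths Wavelengths in nm, strictly monotonic.
#' @param ellipticity Ellipticity values, one per wavelength.
#' @param units `"millidegrees"` (raw instrument ellipticity theta) or
#'   `"molar_ellipticity"` (mean-residue molar ellipticity, deg cm^2 dmol^-1).
#' @param temperature_C Acquisition temperature (deg C).
#' @param meta Optional named list describing the sample (peptide, solvent).
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, ellipticity,
                        units = c("millidegrees", "molar_ellipticity"),
                        temperature_C = 25, meta = list()) {
  units <- match.arg(units)
  wavelengths <- as.numeric(wavelengths)
  ellipticity <- as.numeric(ellipticity)
  if (length(wavelengths) != length(ellipticity))
    ps_stop("wavelength and ellipticity lengths differ", "input_error")
  d <- diff(wavelengths)
  if (length(d) > 0L && !(all(d > 0) || all(d < 0)))
    ps_stop("wavelengths must be strictly monotonic", "input_error")
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity,
                 units = units, temperature_C = temperature_C, meta = meta),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("CD spectrum: %d points, %.1f-%.1f nm, units = %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$units))
  invisible(x)
}

#' CD sample information
#'
#' Metadata required to normalise raw ellipticity: peptide concentration,
#' cuvette path length and number of residues (mean-residue normalisation).
#'
#' @param concentration_molar Peptide concentration in mol/L.
#' @param path_length_cm Cuvette path length in cm (1 mm cell = 0.1).
#' @param n_residues Number of residues in the peptide.
#' @return An object of class `cd_sample_info`.
#' @export
cd_sample_info <- function(concentration_molar, path_length_cm, n_residues) {
  if (!is_scalar_number(concentration_molar) || concentration_molar <= 0 ||
      !is_scalar_number(path_length_cm) || path_length_cm <= 0 ||
      !is.numeric(n_residues) || n_residues <= 0)
    ps_stop("concentration, path length and residue count must be positive",
            "parameter_error")
  structure(list(concentration_molar = concentration_molar,
                 path_length_cm = path_length_cm,
                 n_residues = as.integer(n_residues)),
            class = "cd_sample_info")
}

#' Convert raw ellipticity to mean-residue molar ellipticity
#'
#' Applies `[theta](lambda) = theta_mdeg(lambda) / (10 * C * l * n)` with
#' concentration C in mol/L, path length l in cm and n residues, yielding
#' mean-residue molar ellipticity in deg cm^2 dmol^-1 (per peptide bond, the
#' normalisation assumed by the 222 nm helix estimator).
#'
#' @param spec A `cd_spectrum` in millidegrees.
#' @param info A `cd_sample_info`.
#' @return A `cd_spectrum` in `"molar_ellipticity"` units.
#' @export
to_mean_residue_ellipticity <- function(spec, info) {
  stopifnot(inherits(spec, "cd_spectrum"), inherits(info, "cd_sample_info"))
  if (spec$units != "millidegrees")
    ps_stop("spectrum is not in millidegrees", "parameter_error")
  denom <- 10 * info$concentration_molar * info$path_length_cm * info$n_residues
  out <- spec
  out$ellipticity <- spec$ellipticity / denom
  out$units <- "molar_ellipticity"
  out
}

#' Smooth a CD spectrum
#'
#' Moving-window polynomial (Savitzky-Golay-style) smoother: at each point a
#' polynomial of degree `order` is least-squares fitted to the surrounding
#' `window` points and evaluated at the centre. Near the ends the window
#' shrinks symmetrically so every output point uses only observed data.
#' Reproduces constants and, for `order >= 1`, straight lines exactly.
#'
#' @param spec A `cd_spectrum`.
#' @param window Odd window width in points (default 11).
#' @param order Polynomial degree, `order < window` (default 3).
#' @return A smoothed `cd_spectrum` on the same wavelength grid.
#' @export
smooth_spectrum <- function(spec, window = 11L, order = 3L) {
  stopifnot(inherits(spec, "cd_spectrum"))
  window <- as.integer(window); order <- as.integer(order)
  n <- length(spec$wavelengths)
  if (window %% 2L != 1L || window <= order)
    ps_stop("window must be odd and greater than order", "parameter_error")
  if (window >= n)
    ps_stop("window must be smaller than the number of points", "parameter_error")
  h <- (window - 1L) %/% 2L
  y <- spec$ellipticity
  x <- spec$wavelengths
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)     # shrink symmetrically at the ends
    idx <- (i - hi):(i + hi)
    deg <- min(order, length(idx) - 1L)
    if (deg == 0L) {
      out[i] <- mean(y[idx])
    } else {
      fit <- stats::lm.fit(outer(x[idx] - x[i], 0:deg, `^`), y[idx])
      out[i] <- fit$coefficients[1L]
    }
  }
  res <- spec
  res$ellipticity <- out
  res
}

#' Helix fraction from the 222 nm ellipticity
#'
#' Single-wavelength helix estimator: with `[theta]222` the mean-residue
#' molar ellipticity at 222 nm (deg cm^2 dmol^-1),
#' `percent = 100 * (3000 - [theta]222) / 39000`, i.e. an affine map with
#' the full-coil limit at +3000 and the full-helix limit at -36000.
#' The unrounded percentage is retained; the `rounded` field applies
#' half-away-from-zero integer rounding, the convention used when helicity
#' tables are printed. Values outside [0, 100] are returned unclamped with
#' `range_warning = TRUE`.
#'
#' @param theta222 Mean-residue molar ellipticity at 222 nm.
#' @return An object of class `helix_fraction` with fields `percent`,
#'   `rounded` and `range_warning`.
#' @examples
#' helix_fraction_from_ellipticity(-2178.68)  # ~13%
#' @export
helix_fraction_from_ellipticity <- function(theta222) {
  if (!is_scalar_number(theta222))
    ps_stop("theta222 must be a finite number", "input_error")
  pct <- 100 * (3000 - theta222) / 39000
  structure(list(percent = pct,
                 rounded = round_half_away(pct),
                 range_warning = pct < 0 || pct > 100),
            class = "helix_fraction")
}

#' @export
print.helix_fraction <- function(x, ...) {
  cat(sprintf("%% helix from [theta]222: %.2f%% (rounded %d%%)%s\n",
              x$percent, as.integer(x$rounded),
              if (x$range_warning) "  [outside 0-100]" else ""))
  invisible(x)
}

#' Ellipticity at a given wavelength
#'
#' Linear interpolation on the spectrum's grid (exact where the grid
#' contains the wavelength).
#'
#' @param spec A `cd_spectrum`.
#' @param lambda Wavelength in nm, inside the covered range.
#' @return Ellipticity value in the spectrum's units.
#' @export
ellipticity_at <- function(spec, lambda = 222) {
  stopifnot(inherits(spec, "cd_spectrum"))
  if (lambda < min(spec$wavelengths) || lambda > max(spec$wavelengths))
    ps_stop(sprintf("wavelength %.1f nm outside spectrum coverage", lambda),
            "coverage_error")
  stats::approx(spec$wavelengths, spec$ellipticity, xout = lambda)$y
}

# local minima of y (interior points strictly below both neighbours,
# assessed on a lightly smoothed copy to suppress point noise)
.local_minima <- function(x, y) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1L)
  idx <- i[y[i] < y[i - 1L] & y[i] < y[i + 1L]]
  x[idx]
}

#' Classify the shape of a CD spectrum
#'
#' Coarse shape classes used when screening peptide spectra:
#' `random_coil` for a single dominant minimum near 197 nm (global minimum
#' within 195-200 nm, no 208/222 nm double minimum), `helical` for the
#' canonical alpha-helix signature (local minima within 3 nm of 208 and
#' 222 nm plus a positive band below 195 nm), `other` for anything else
#' (including a flat spectrum).
#'
#' @param spec A `cd_spectrum` covering at least 190-260 nm.
#' @return One of `"random_coil"`, `"helical"`, `"other"`.
#' @export
classify_spectrum <- function(spec) {
  stopifnot(inherits(spec, "cd_spectrum"))
  wl <- spec$wavelengths
  if (min(wl) > 190 || max(wl) < 260)
    ps_stop("spectrum must cover 190-260 nm for classification",
            "coverage_error")
  y <- spec$ellipticity
  if (all(abs(y) < .Machine$double.eps^0.5)) return("other")
  minima <- .local_minima(wl, y)
  has208 <- any(abs(minima - 208) <= 3)
  has222 <- any(abs(minima - 222) <= 3)
  below195 <- y[wl < 195]
  pos_band <- length(below195) > 0L && max(below195) > 0
  if (has208 && has222 && pos_band) return("helical")
  gmin <- wl[which.min(y)]
  if (gmin >= 195 && gmin <= 200 && !(has208 && has222)) return("random_coil")
  "other"
}

#' Read / write a CD spectrum as two-column delimited text
#'
#' Format: optional comment/header lines starting with `#` (a
#' `# units: <units>` line is honoured), then `wavelength_nm<sep>ellipticity`
#' rows.
#'
#' @param path File path.
#' @param units Units to assume when the file carries no units header.
#' @return `read_cd_table()` returns a `cd_spectrum`; `write_cd_table()`
#'   returns `path` invisibly.
#' @export
read_cd_table <- function(path, units = "millidegrees") {
  if (!file.exists(path))
    ps_stop(sprintf("CD file not found: %s", path), "io_error")
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  um <- grep("units:", hdr, value = TRUE)
  if (length(um) > 0L)
    units <- trimws(sub(".*units:", "", um[1L]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = body, header = FALSE,
                          col.names = c("wavelength_nm", "ellipticity"))
  cd_spectrum(df$wavelength_nm, df$ellipticity, units = units)
}

#' @rdname read_cd_table
#' @param spec A `cd_spectrum` to write.
#' @export
write_cd_table <- function(spec, path) {
  stopifnot(inherits(spec, "cd_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", spec$units), con)
  writeLines(sprintf("%.4f\t%.6f", spec$wavelengths, spec$ellipticity), con)
  invisible(path)
}
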