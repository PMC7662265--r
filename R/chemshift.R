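# Secondary chemical shifts, helical-segment detection, and two-state
# helix populations from segment-averaged deviations.

NUCLEI <- c("HA", "HN", "CA")

# Calibrated full-helix limiting secondary shifts (ppm). In the two-state
# helix-coil model a residue's secondary shift interpolates linearly between
# 0 (coil) and the limit below (full helix); populations are the ratio.
HELIX_LIMITS <- c(HA = -0.39, CA = +3.1)

# Stated per-measurement experimental errors (ppm): 0.01 for 1H, 0.1 for 13C.
MEASUREMENT_ERRORS <- c(HA = 0.01, CA = 0.1)

AA3 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
         HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
         PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
         TRP = "W", TYR = "Y")
AA1TO3 <- stats::setNames(names(AA3), AA3)

#' Construct a chemical-shift table
#'
#' Per-residue, per-nucleus chemical shifts for one peptide under one
#' experimental condition. Nuclei are `HA` (Halpha), `HN` (backbone amide
#' proton) and `CA` (Calpha). Validation enforces: residues within the
#' peptide, no amide-proton entry on proline, finite values, 1H shifts in
#' [-2, 12] ppm and 13C shifts in [10, 80] ppm, and no duplicated
#' (residue, nucleus) pairs.
#'
#' @param peptide A `peptide`.
#' @param shifts Data frame with columns `number` (absolute residue number),
#'   `nucleus` (one of `HA`, `HN`, `CA`) and `ppm`.
#' @param condition Condition label, e.g. `"H2O"`, `"30% TFE"`, `"30 mM DPC"`.
#' @param temperature_C,pH Sample conditions.
#' @return An object of class `shift_table`.
#' @export
shift_table <- function(peptide, shifts, condition = "H2O",
                        temperature_C = 25, pH = 5.5) {
  stopifnot(inherits(peptide, "peptide"), is.data.frame(shifts))
  need <- c("number", "nucleus", "ppm")
  if (!all(need %in% names(shifts)))
    ps_stop("shifts must have columns number, nucleus, ppm", "format_error")
  shifts <- shifts[, need]
  shifts$number <- as.integer(shifts$number)
  shifts$nucleus <- as.character(shifts$nucleus)
  shifts$ppm <- as.numeric(shifts$ppm)
  if (!all(shifts$nucleus %in% NUCLEI))
    ps_stop(sprintf("unknown nucleus: %s",
                    paste(setdiff(shifts$nucleus, NUCLEI), collapse = ",")),
            "format_error")
  out <- setdiff(shifts$number, peptide$numbers)
  if (length(out) > 0L)
    ps_stop(sprintf("shift table refers to residue(s) %s outside peptide %s",
                    paste(sort(out), collapse = ","), peptide$name),
            "reconciliation_error")
  key <- paste(shifts$number, shifts$nucleus)
  if (anyDuplicated(key))
    ps_stop(sprintf("duplicate (residue, nucleus) entries: %s",
                    paste(unique(key[duplicated(key)]), collapse = "; ")),
            "format_error")
  pro <- peptide$numbers[peptide$sequence == "P"]
  if (any(shifts$number %in% pro & shifts$nucleus == "HN"))
    ps_stop("proline residues cannot carry an HN shift", "format_error")
  if (!all(is.finite(shifts$ppm)))
    ps_stop("all shift values must be finite", "format_error")
  is_c <- shifts$nucleus == "CA"
  if (any(shifts$ppm[!is_c] < -2 | shifts$ppm[!is_c] > 12))
    ps_stop("1H shifts must lie within [-2, 12] ppm", "format_error")
  if (any(shifts$ppm[is_c] < 10 | shifts$ppm[is_c] > 80))
    ps_stop("13C shifts must lie within [10, 80] ppm", "format_error")
  shifts <- shifts[order(shifts$number, match(shifts$nucleus, NUCLEI)), ]
  rownames(shifts) <- NULL
  structure(list(peptide = peptide, condition = condition,
                 temperature_C = temperature_C, pH = pH, shifts = shifts),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("Shift table: %s in %s (%d entries, %.0f C, pH %.1f)\n",
              x$peptide$name, x$condition, nrow(x$shifts),
              x$temperature_C, x$pH))
  invisible(x)
}

#' Look up an observed shift
#' @param table A `shift_table`.
#' @param number Absolute residue number.
#' @param nucleus `"HA"`, `"HN"` or `"CA"`.
#' @return The shift in ppm, or `NA` if absent.
#' @export
observed_shift <- function(table, number, nucleus) {
  s <- table$shifts
  hit <- s$number == number & s$nucleus == nucleus
  if (!any(hit)) NA_real_ else s$ppm[hit]
}

#' Read a chemical-shift table
#'
#' Two on-disk formats are supported. `csv`: columns `residue_number`,
#' `residue_code`, `nucleus`, `shift_ppm`. `nmrstar`: a minimal NMR-STAR
#' `_Atom_chem_shift` loop (sequence code, comp ID, atom ID, value) as used
#' for BMRB depositions; atom IDs `H` and `HN` map to the amide proton,
#' `HA` and `CA` to themselves, and any other atom is ignored with a
#' message giving the count.
#'
#' @param path File path.
#' @param peptide The `peptide` the shifts belong to (used for validation).
#' @param format `"csv"` or `"nmrstar"`.
#' @param condition,temperature_C,pH Passed to [shift_table()].
#' @return A validated `shift_table`.
#' @export
read_shift_table <- function(path, peptide, format = c("csv", "nmrstar"),
                             condition = "H2O", temperature_C = 25, pH = 5.5) {
  format <- match.arg(format)
  if (!file.exists(path))
    ps_stop(sprintf("shift file not found: %s", path), "io_error")
  df <- switch(format,
               csv = .read_shift_csv(path, peptide),
               nmrstar = .read_shift_star(path))
  shift_table(peptide, df, condition = condition,
              temperature_C = temperature_C, pH = pH)
}

.read_shift_csv <- function(path, peptide) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_number", "nucleus", "shift_ppm")
  if (!all(need %in% names(df)))
    ps_stop("csv must have columns residue_number, residue_code, nucleus, shift_ppm",
            "format_error")
  if ("residue_code" %in% names(df)) {
    idx <- match(as.integer(df$residue_number), peptide$numbers)
    mism <- which(!is.na(idx) & df$residue_code != peptide$sequence[idx])
    if (length(mism) > 0L)
      ps_stop(sprintf("residue code mismatch at residue(s) %s",
                      paste(df$residue_number[mism], collapse = ",")),
              "reconciliation_error")
  }
  data.frame(number = df$residue_number, nucleus = df$nucleus,
             ppm = df$shift_ppm)
}

# Minimal NMR-STAR chemical-shift loop reader: finds the loop whose tags
# start with _Atom_chem_shift., reads whitespace-delimited rows until stop_.
.read_shift_star <- function(path) {
  lines <- trimws(readLines(path))
  tag_idx <- grep("^_Atom_chem_shift\\.", lines)
  if (length(tag_idx) == 0L)
    ps_stop("no _Atom_chem_shift loop found", "format_error")
  tags <- sub("^_Atom_chem_shift\\.", "", lines[tag_idx])
  first_data <- max(tag_idx) + 1L
  rows <- character(0)
  for (i in first_data:length(lines)) {
    ln <- lines[i]
    if (ln == "stop_" || startsWith(ln, "_") || ln == "loop_") break
    if (nzchar(ln) && !startsWith(ln, "#")) rows <- c(rows, ln)
  }
  if (length(rows) == 0L)
    ps_stop("empty _Atom_chem_shift loop", "format_error")
  mat <- utils::read.table(text = rows, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(mat) != length(tags))
    ps_stop("NMR-STAR loop row width does not match its tags", "format_error")
  names(mat) <- tags
  seq_col <- intersect(c("Seq_ID", "Comp_index_ID"), tags)[1L]
  if (is.na(seq_col) || !all(c("Atom_ID", "Val") %in% tags))
    ps_stop("loop must carry a sequence code, Atom_ID and Val", "format_error")
  atom <- toupper(mat$Atom_ID)
  nuc <- ifelse(atom %in% c("H", "HN"), "HN",
                ifelse(atom %in% c("HA", "CA"), atom, NA))
  dropped <- sum(is.na(nuc))
  if (dropped > 0L)
    message(sprintf("read_shift_table: ignored %d entr%s for unsupported atoms",
                    dropped, if (dropped == 1L) "y" else "ies"))
  keep <- !is.na(nuc)
  data.frame(number = as.integer(mat[[seq_col]][keep]),
             nucleus = nuc[keep], ppm = as.numeric(mat$Val[keep]))
}

#' Write a chemical-shift table
#'
#' Writes the same formats [read_shift_table()] consumes: `csv` with columns
#' `residue_number`, `residue_code`, `nucleus`, `shift_ppm`, or a minimal
#' NMR-STAR `_Atom_chem_shift` loop.
#'
#' @param table A `shift_table`.
#' @param path Output path.
#' @param format `"csv"` or `"nmrstar"`.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(table, path, format = c("csv", "nmrstar")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "shift_table"))
  s <- table$shifts
  codes <- residue_code(table$peptide, s$number)
  if (format == "csv") {
    df <- data.frame(residue_number = s$number, residue_code = codes,
                     nucleus = s$nucleus, shift_ppm = s$ppm)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    atom <- ifelse(s$nucleus == "HN", "H", s$nucleus)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_shifts", "", "loop_",
                 "  _Atom_chem_shift.ID",
                 "  _Atom_chem_shift.Seq_ID",
                 "  _Atom_chem_shift.Comp_ID",
                 "  _Atom_chem_shift.Atom_ID",
                 "  _Atom_chem_shift.Val"), con)
    writeLines(sprintf("  %d %d %s %s %.4f", seq_len(nrow(s)), s$number,
                       AA1TO3[codes], atom, s$ppm), con)
    writeLines("stop_", con)
  }
  invisible(path)
}

#' Secondary chemical shifts against a random-coil reference
#'
#' Computes `delta(i) = delta_obs(i) - delta_RC(aa_i)` residue-wise for the
#' requested nucleus. Residues without an observed shift are absent from the
#' profile (never zero-filled). Negative Halpha and positive Calpha
#' deviations indicate alpha-helix.
#'
#' @param table A `shift_table`.
#' @param rc A `random_coil_table`.
#' @param nucleus `"HA"` or `"CA"` (secondary-shift profiles are defined for
#'   these two nuclei only).
#' @return An object of class `delta_profile`: `nucleus`, `values` (numeric
#'   vector named by absolute residue number), `peptide`, `source`
#'   (condition and reference-set identifiers).
#' @export
secondary_shifts <- function(table, rc, nucleus = c("HA", "CA")) {
  stopifnot(inherits(table, "shift_table"), inherits(rc, "random_coil_table"))
  if (length(nucleus) == 1L && identical(nucleus, "HN"))
    ps_stop("secondary-shift profiles are defined for HA and CA only",
            "unsupported_error")
  nucleus <- match.arg(nucleus)
  s <- table$shifts[table$shifts$nucleus == nucleus, ]
  codes <- residue_code(table$peptide, s$number)
  vals <- s$ppm - rc_shift(rc, codes, nucleus)
  structure(list(nucleus = nucleus,
                 values = stats::setNames(vals, s$number),
                 peptide = table$peptide,
                 source = list(condition = table$condition, rc_set = rc$name)),
            class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("Secondary shifts (delta-delta %s) for %s in %s [RC set: %s]\n",
              x$nucleus, x$peptide$name, x$source$condition, x$source$rc_set))
  print(round(x$values, 3))
  invisible(x)
}

#' Define a helix segment
#' @param first,last Absolute residue numbers, `first < last`.
#' @return An object of class `helix_segment`.
#' @export
helix_segment <- function(first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (!(first < last))
    ps_stop("a helix segment needs first < last", "input_error")
  structure(list(first = first, last = last), class = "helix_segment")
}

#' @export
format.helix_segment <- function(x, ...) sprintf("%d-%d", x$first, x$last)

#' @export
print.helix_segment <- function(x, ...) {
  cat("Helix segment", format(x), "\n"); invisible(x)
}

#' Detect helical segments from an Halpha secondary-shift profile
#'
#' A residue is helical when its Halpha secondary shift lies below the
#' random-coil band, i.e. `delta_HA < -rc_band`. Segments are maximal runs
#' of at least `min_length` consecutive residues satisfying this; any single
#' interior residue at or above `-rc_band` terminates a run (it acts as a
#' helix breaker), as does a residue missing from the profile.
#'
#' @param profile A `delta_profile` with `nucleus == "HA"`.
#' @param rc_band Half-width of the random-coil band in ppm (default 0.05,
#'   i.e. |delta_HA| <= 0.05 ppm is conformationally uninformative).
#' @param min_length Minimum run length in residues (default 3).
#' @return A list of `helix_segment` objects (possibly empty).
#' @export
detect_helical_segments <- function(profile, rc_band = 0.05, min_length = 3L) {
  stopifnot(inherits(profile, "delta_profile"))
  if (profile$nucleus != "HA")
    ps_stop("segment detection operates on HA profiles", "unsupported_error")
  v <- profile$values
  if (length(v) == 0L) return(list())
  nums <- as.integer(names(v))
  o <- order(nums)
  nums <- nums[o]; v <- v[o]
  segs <- list()
  run_start <- NA_integer_; prev <- NA_integer_
  close_run <- function(run_start, prev) {
    if (!is.na(run_start) && prev - run_start + 1L >= min_length)
      segs[[length(segs) + 1L]] <<- helix_segment(run_start, prev)
  }
  for (k in seq_along(nums)) {
    helical <- v[k] < -rc_band
    contiguous <- !is.na(prev) && nums[k] == prev + 1L
    if (helical && (is.na(run_start) || !contiguous)) {
      close_run(run_start, prev)
      run_start <- nums[k]
    } else if (!helical) {
      close_run(run_start, prev)
      run_start <- NA_integer_
    }
    prev <- nums[k]
  }
  close_run(run_start, prev)
  segs
}

#' Average secondary shift over a segment
#'
#' Arithmetic mean of the profile values for residues present within
#' `[first, last]`; missing residues are simply not included.
#'
#' @param profile A `delta_profile`.
#' @param segment A `helix_segment`.
#' @return Mean secondary shift in ppm.
#' @export
segment_average <- function(profile, segment) {
  stopifnot(inherits(profile, "delta_profile"),
            inherits(segment, "helix_segment"))
  nums <- as.integer(names(profile$values))
  inside <- nums >= segment$first & nums <= segment$last
  if (!any(inside))
    ps_stop(sprintf("no %s data within segment %s", profile$nucleus,
                    format(segment)), "empty_segment_error")
  mean(profile$values[inside])
}

#' Helix population from an averaged secondary shift
#'
#' Two-state helix-coil conversion: `percent = 100 * avg_delta / limit`,
#' where the full-helix limiting secondary shifts are -0.39 ppm (Halpha) and
#' +3.1 ppm (Calpha). The propagated uncertainty is
#' `100 * measurement_error / |limit|` with per-measurement errors of
#' 0.01 ppm (1H) and 0.1 ppm (13C). Percentages outside [0, 100] are
#' returned unclamped with a range warning flag.
#'
#' @param avg_delta Segment-averaged secondary shift in ppm.
#' @param nucleus `"HA"` or `"CA"`.
#' @param segment Optional `helix_segment` the average was taken over.
#' @param limits Named full-helix limits (ppm); override for sensitivity
#'   analyses.
#' @param measurement_errors Named per-measurement errors (ppm).
#' @return An object of class `population_estimate` with fields `percent`,
#'   `rounded`, `error_percent`, `nucleus`, `segment`, `range_warning`.
#' @examples
#' helix_population(-0.24, "HA")   # ~62%
#' helix_population(+2.50, "CA")   # ~81%
#' @export
helix_population <- function(avg_delta, nucleus = c("HA", "CA"),
                             segment = NULL, limits = HELIX_LIMITS,
                             measurement_errors = MEASUREMENT_ERRORS) {
  nucleus <- match.arg(nucleus)
  if (!is_scalar_number(avg_delta))
    ps_stop("avg_delta must be a finite number", "input_error")
  lim <- limits[[nucleus]]
  if (!is_scalar_number(lim) || lim == 0)
    ps_stop("full-helix limit must be nonzero", "parameter_error")
  pct <- 100 * avg_delta / lim
  err <- 100 * measurement_errors[[nucleus]] / abs(lim)
  structure(list(percent = pct, rounded = round_half_away(pct),
                 error_percent = err, nucleus = nucleus, segment = segment,
                 range_warning = pct < 0 || pct > 100),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  seg <- if (!is.null(x$segment)) paste0(" over ", format(x$segment)) else ""
  cat(sprintf("Helix population (%s%s): %.1f%% +/- %.1f%%%s\n",
              x$nucleus, seg, x$percent, x$error_percent,
              if (x$range_warning) "  [outside 0-100]" else ""))
  invisible(x)
}

#' Combine Halpha- and Calpha-derived populations
#'
#' The combined estimate is the mean of the two integer-rounded percentages;
#' its uncertainty is the population standard deviation of the pair, i.e.
#' half their absolute difference — the convention used when the two
#' nucleus-specific estimates are averaged into a single table cell.
#'
#' @param p_ha,p_ca `population_estimate` objects for the same segment.
#' @return A `population_estimate` with `nucleus = "combined"`.
#' @examples
#' ha <- helix_population(-0.24, "HA"); ca <- helix_population(2.50, "CA")
#' combine_populations(ha, ca)
#' @export
combine_populations <- function(p_ha, p_ca) {
  stopifnot(inherits(p_ha, "population_estimate"),
            inherits(p_ca, "population_estimate"))
  sa <- p_ha$segment; sb <- p_ca$segment
  if (!is.null(sa) && !is.null(sb) &&
      (sa$first != sb$first || sa$last != sb$last))
    ps_stop("populations to combine must refer to the same segment",
            "pairing_error")
  r1 <- p_ha$rounded; r2 <- p_ca$rounded
  pct <- mean(c(r1, r2))
  err <- abs(r1 - r2) / 2
  structure(list(percent = pct, rounded = round_half_away(pct),
                 error_percent = err, nucleus = "combined",
                 segment = sa %||% sb,
                 range_warning = pct < 0 || pct > 100),
            class = "population_estimate")
}
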