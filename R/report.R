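# Condition-comparison report: drives the full analysis (CD helicity,
# secondary shifts, segment detection, populations, CSP) from a single
# declarative YAML config and assembles a summary table per peptide and
# condition.

.stage_error <- function(stage, msg) {
  ps_stop(sprintf("[%s] %s", stage, msg), "stage_error")
}

.resolve <- function(path, base) {
  if (is.null(path)) return(NULL)
  if (file.exists(path)) return(path)
  fp <- file.path(base, path)
  if (file.exists(fp)) return(fp)
  path   # caller reports the missing file
}

#' Run the full analysis pipeline from a config file
#'
#' The YAML config names peptide definition files, per-condition inputs
#' (CD spectrum, shift table, optional mixture table) and options. For each
#' condition the pipeline: converts/interpolates the CD spectrum and
#' estimates helicity at 222 nm; computes HA and CA secondary-shift
#' profiles; detects helical segments from the HA profile; averages both
#' profiles per segment and converts the averages to helix populations,
#' plus their combined estimate; and, when a mixture table is given,
#' computes the weighted CSP profile and flags interacting residues. All
#' thresholds and calibration constants in force are echoed in the report
#' header. Reruns on the same inputs are deterministic.
#'
#' Config layout (YAML):
#' \preformatted{
#' seed: 1
#' options: {rc_set: wishart1995, rc_band: 0.05, min_length: 3,
#'           csp_policy: mean_plus_sd, csp_cutoff: 0.02}
#' peptides: {CB1: cb1.json}
#' conditions:
#'   - {peptide: CB1, name: TFE,
#'      cd: {file: cd.csv, units: millidegrees,
#'           concentration_molar: 5.0e-5, path_length_cm: 0.1},
#'      shifts: {file: shifts.csv, format: csv},
#'      mixture: {file: mix.csv, format: csv}}
#' }
#'
#' @param config Path to the YAML config file (relative input paths are
#'   resolved against the config's directory).
#' @return An object of class `analysis_report` with `rows` (one per
#'   peptide/condition/segment), `csp` (flagged residues per condition),
#'   `header` (options and calibration constants used).
#' @export
run_pipeline <- function(config) {
  if (!file.exists(config))
    .stage_error("config", sprintf("config file not found: %s", config))
  cfg <- yaml::read_yaml(config)
  base <- dirname(normalizePath(config))
  opts <- cfg$options %||% list()
  rc_set <- opts$rc_set %||% "wishart1995"
  rc_band <- opts$rc_band %||% 0.05
  min_length <- opts$min_length %||% 3L
  csp_policy <- opts$csp_policy %||% "mean_plus_sd"
  csp_cutoff <- opts$csp_cutoff %||% 0.02
  rc <- random_coil_table(rc_set)

  peptides <- lapply(cfg$peptides, function(p) {
    fp <- .resolve(p, base)
    if (!file.exists(fp))
      .stage_error("peptides", sprintf("peptide definition not found: %s", p))
    read_peptide(fp)
  })

  rows <- list(); csp_out <- list()
  for (cond in cfg$conditions) {
    pep <- peptides[[cond$peptide]]
    if (is.null(pep))
      .stage_error("conditions",
                   sprintf("condition refers to unknown peptide '%s'",
                           cond$peptide))
    label <- cond$name %||% "unnamed"

    theta222 <- NA_real_; cd_pct <- NA_real_
    if (!is.null(cond$cd)) {
      fp <- .resolve(cond$cd$file, base)
      if (!file.exists(fp))
        .stage_error("cd", sprintf("CD file not found: %s", cond$cd$file))
      spec <- read_cd_table(fp, units = cond$cd$units %||% "millidegrees")
      if (spec$units == "millidegrees") {
        info <- cd_sample_info(cond$cd$concentration_molar,
                               cond$cd$path_length_cm,
                               length(pep))
        spec <- to_mean_residue_ellipticity(spec, info)
      }
      theta222 <- ellipticity_at(spec, 222)
      cd_pct <- helix_fraction_from_ellipticity(theta222)$rounded
    }

    seg_rows <- list()
    if (!is.null(cond$shifts)) {
      fp <- .resolve(cond$shifts$file, base)
      if (!file.exists(fp))
        .stage_error("shifts",
                     sprintf("shift file not found: %s", cond$shifts$file))
      tab <- read_shift_table(fp, pep,
                              format = cond$shifts$format %||% "csv",
                              condition = label)
      pr_ha <- secondary_shifts(tab, rc, "HA")
      pr_ca <- secondary_shifts(tab, rc, "CA")
      segs <- detect_helical_segments(pr_ha, rc_band = rc_band,
                                      min_length = min_length)
      for (seg in segs) {
        av_ha <- segment_average(pr_ha, seg)
        av_ca <- segment_average(pr_ca, seg)
        p_ha <- helix_population(av_ha, "HA", segment = seg)
        p_ca <- helix_population(av_ca, "CA", segment = seg)
        comb <- combine_populations(p_ha, p_ca)
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          peptide = pep$name, condition = label,
          theta222 = theta222, cd_percent = cd_pct,
          segment = format(seg),
          av_dHA = av_ha, pct_HA = p_ha$rounded,
          av_dCA = av_ca, pct_CA = p_ca$rounded,
          combined = comb$percent, combined_err = comb$error_percent,
          stringsAsFactors = FALSE)
      }
      if (length(segs) == 0L)
        seg_rows[[1L]] <- data.frame(
          peptide = pep$name, condition = label,
          theta222 = theta222, cd_percent = cd_pct, segment = NA_character_,
          av_dHA = NA_real_, pct_HA = NA_real_, av_dCA = NA_real_,
          pct_CA = NA_real_, combined = NA_real_, combined_err = NA_real_,
          stringsAsFactors = FALSE)

      if (!is.null(cond$mixture)) {
        fpm <- .resolve(cond$mixture$file, base)
        if (!file.exists(fpm))
          .stage_error("csp",
                       sprintf("mixture file not found: %s",
                               cond$mixture$file))
        mix <- read_shift_table(fpm, pep,
                                format = cond$mixture$format %||% "csv",
                                condition = paste0(label, "+mixture"))
        prof <- weighted_csp(tab, mix)
        flags <- flag_interacting_residues(prof, policy = csp_policy,
                                           cutoff = csp_cutoff)
        csp_out[[paste(pep$name, label, sep = "/")]] <- flags
      }
    } else {
      seg_rows[[1L]] <- data.frame(
        peptide = pep$name, condition = label,
        theta222 = theta222, cd_percent = cd_pct, segment = NA_character_,
        av_dHA = NA_real_, pct_HA = NA_real_, av_dCA = NA_real_,
        pct_CA = NA_real_, combined = NA_real_, combined_err = NA_real_,
        stringsAsFactors = FALSE)
    }
    rows <- c(rows, seg_rows)
  }

  structure(list(
    rows = do.call(rbind, rows),
    csp = csp_out,
    header = list(rc_set = rc_set, rc_band = rc_band,
                  min_length = min_length,
                  helix_limits = HELIX_LIMITS,
                  measurement_errors = MEASUREMENT_ERRORS,
                  csp_policy = csp_policy, csp_cutoff = csp_cutoff)
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  h <- x$header
  cat("Analysis report\n")
  cat(sprintf("  RC set %s | RC band %.2f ppm | min run %d | limits HA %.2f / CA %.1f ppm\n",
              h$rc_set, h$rc_band, h$min_length,
              h$helix_limits[["HA"]], h$helix_limits[["CA"]]))
  cat(sprintf("  CSP policy %s (floor %.3f ppm)\n\n", h$csp_policy,
              h$csp_cutoff))
  print(x$rows, digits = 4)
  if (length(x$csp) > 0L) {
    cat("\nFlagged interface residues:\n")
    for (nm in names(x$csp)) {
      r <- x$csp[[nm]]$residues
      cat(sprintf("  %s: %s\n", nm,
                  if (nrow(r)) paste0(r$code, r$number, collapse = ", ")
                  else "none"))
    }
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @param format One or more of `"csv"`, `"json"`, `"text"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, format = c("csv", "text")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format, c("csv", "json", "text"), several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("csv" %in% format) {
    p <- file.path(dir, "report.csv")
    utils::write.csv(report$rows, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(list(header = report$header, rows = report$rows,
                              csp = lapply(report$csp, function(s)
                                list(policy = s$policy,
                                     numbers = s$residues$number,
                                     codes = s$residues$code))),
                         p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if ("text" %in% format) {
    p <- file.path(dir, "report.txt")
    con <- file(p, "w")
    sink(con); print(report); sink()
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}
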