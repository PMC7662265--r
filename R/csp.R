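# Chemical-shift-perturbation (CSP) mapping of a peptide-peptide interface:
# weighted differences between free and mixture shift tables, and selection
# of the "active" residues that seed data-driven docking restraints.

#' Weighted chemical-shift perturbation profile
#'
#' For each residue the free-vs-mixture differences of the Halpha, amide
#' proton and Calpha shifts are combined as
#' `delta_w = sqrt(dHA^2 + dHN^2 + dCA^2 / 4)`,
#' the 1/4 weight down-scaling the carbon axis to the proton dispersion.
#' Only nuclei present in both tables contribute; a missing nucleus
#' contributes zero to the sum and is recorded as `NA` in the component
#' table (so proline, which has no amide proton, uses HA/CA only). A residue
#' with no shared nucleus at all is omitted from the profile with a warning.
#'
#' @param free `shift_table` of the isolated peptide.
#' @param mixture `shift_table` of the same peptide in the peptide mixture.
#' @return An object of class `csp_profile`: `values` (delta_w, named by
#'   absolute residue number), `components` (data frame of per-residue
#'   dHA/dHN/dCA with `NA` for absent nuclei), `peptide`, `free_id`,
#'   `mixture_id`.
#' @export
weighted_csp <- function(free, mixture) {
  stopifnot(inherits(free, "shift_table"), inherits(mixture, "shift_table"))
  if (!identical(free$peptide$sequence, mixture$peptide$sequence) ||
      !identical(free$peptide$numbers, mixture$peptide$numbers))
    ps_stop("free and mixture tables must describe the same peptide",
            "pairing_error")
  nums <- sort(unique(c(free$shifts$number, mixture$shifts$number)))
  comp <- matrix(NA_real_, nrow = length(nums), ncol = 3,
                 dimnames = list(nums, c("dHA", "dHN", "dCA")))
  for (i in seq_along(nums)) {
    for (j in seq_along(NUCLEI)) {
      a <- observed_shift(mixture, nums[i], NUCLEI[j])
      b <- observed_shift(free, nums[i], NUCLEI[j])
      if (!is.na(a) && !is.na(b)) comp[i, j] <- a - b
    }
  }
  shared <- rowSums(!is.na(comp)) > 0L
  if (any(!shared))
    ps_warn(sprintf("residue(s) %s share no nucleus between the tables; omitted",
                    paste(nums[!shared], collapse = ",")))
  comp <- comp[shared, , drop = FALSE]
  nums <- nums[shared]
  z <- comp; z[is.na(z)] <- 0
  dw <- sqrt(z[, "dHA"]^2 + z[, "dHN"]^2 + z[, "dCA"]^2 / 4)
  structure(list(values = stats::setNames(as.numeric(dw), nums),
                 components = data.frame(number = nums, comp,
                                         row.names = NULL),
                 peptide = free$peptide,
                 free_id = free$condition, mixture_id = mixture$condition),
            class = "csp_profile")
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("CSP profile for %s (free: %s vs mixture: %s), %d residues\n",
              x$peptide$name, x$free_id, x$mixture_id, length(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Flag interacting residues from a CSP profile
#'
#' Residues whose weighted perturbation is "significant" become the active
#' residues for data-driven docking. Two policies: `mean_plus_sd` flags
#' `delta_w > max(mean + 1*SD, cutoff)` (the fixed `cutoff` acts as a floor,
#' so a flat profile flags nothing), and `fixed_cutoff` flags
#' `delta_w > cutoff`. The policy applied is recorded verbatim in the
#' result for provenance.
#'
#' @param profile A `csp_profile`.
#' @param policy `"mean_plus_sd"` (default) or `"fixed_cutoff"`.
#' @param cutoff Floor / threshold in ppm (default 0.02).
#' @return An object of class `residue_set`: data frame `residues`
#'   (`number`, `code`), `peptide` name, `policy` description string.
#' @export
flag_interacting_residues <- function(profile,
                                      policy = c("mean_plus_sd", "fixed_cutoff"),
                                      cutoff = 0.02) {
  stopifnot(inherits(profile, "csp_profile"))
  policy <- match.arg(policy)
  v <- profile$values
  if (length(v) == 0L)
    ps_stop("cannot flag residues from an empty CSP profile", "input_error")
  thr <- switch(policy,
    mean_plus_sd = {
      sdv <- if (length(v) > 1L) stats::sd(v) else 0
      max(mean(v) + sdv, cutoff)
    },
    fixed_cutoff = cutoff
  )
  sel <- v > thr
  nums <- as.integer(names(v)[sel])
  structure(list(
    residues = data.frame(number = nums,
                          code = if (length(nums)) residue_code(profile$peptide, nums)
                                 else character(0),
                          stringsAsFactors = FALSE),
    peptide = profile$peptide$name,
    policy = sprintf("%s (threshold %.4f ppm)", policy, thr)
  ), class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("Active residues of %s [%s]:", x$peptide, x$policy))
  if (nrow(x$residues) == 0L) cat(" none\n")
  else cat("", paste0(x$residues$code, x$residues$number, collapse = ", "), "\n")
  invisible(x)
}

#' Export / read an active-residue list
#'
#' Writes twin files: a plain-text list (`<path>.txt`) with one
#' `code<number>` per line and a JSON file (`<path>.json`) carrying the
#' peptide name, residue numbers, codes and the selection policy. Output is
#' deterministic (residues sorted by number).
#'
#' @param set A `residue_set`.
#' @param path Output stem; `.txt` and `.json` are appended.
#' @return Invisibly, the two paths written.
#' @export
export_active_residues <- function(set, path) {
  stopifnot(inherits(set, "residue_set"))
  o <- order(set$residues$number)
  res <- set$residues[o, , drop = FALSE]
  txt <- paste0(path, ".txt"); js <- paste0(path, ".json")
  lines <- c(sprintf("# active residues of %s", set$peptide),
             sprintf("# policy: %s", set$policy),
             if (nrow(res)) paste0(res$code, res$number))
  writeLines(lines, txt)
  jsonlite::write_json(list(peptide = set$peptide, policy = set$policy,
                            numbers = res$number, codes = res$code),
                       js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(txt, js))
}

#' @rdname export_active_residues
#' @export
read_active_residues <- function(path) {
  js <- if (endsWith(path, ".json")) path else paste0(path, ".json")
  if (!file.exists(js))
    ps_stop(sprintf("active-residue file not found: %s", js), "io_error")
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  structure(list(
    residues = data.frame(number = as.integer(obj$numbers %||% integer(0)),
                          code = as.character(obj$codes %||% character(0)),
                          stringsAsFactors = FALSE),
    peptide = obj$peptide, policy = obj$policy
  ), class = "residue_set")
}
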