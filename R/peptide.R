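# Peptide definitions: capped sequences with absolute residue numbering and
# optional GPCR (Ballesteros-Weinstein) position labels.

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Define a peptide
#'
#' Creates a `peptide` object: a one-letter sequence with absolute residue
#' numbering starting at `start_number` and optional terminal modifications.
#' Absolute (literature) residue numbers are the canonical coordinate used
#' by every downstream analysis; internal positions never appear in outputs.
#'
#' @param name Peptide identifier, e.g. `"CB1"`.
#' @param sequence One-letter amino-acid string (20 canonical codes only).
#' @param start_number Absolute number of the first residue.
#' @param n_term_mod `"free"` or `"acetyl"` (N-terminal acetylation).
#' @param c_term_mod `"free"` or `"amide"` (C-terminal amidation).
#' @return An object of class `peptide` with fields `name`, `sequence`
#'   (character vector of residues), `numbers` (absolute residue numbers),
#'   `n_term_mod`, `c_term_mod`, `bw_labels` (named character vector,
#'   initially empty).
#' @examples
#' cb1 <- parse_peptide("CB1", "TVNPIIYALRSKDLRHAFR", 391,
#'                      n_term_mod = "acetyl", c_term_mod = "amide")
#' cb1
#' @export
parse_peptide <- function(name, sequence, start_number = 1L,
                          n_term_mod = c("free", "acetyl"),
                          c_term_mod = c("free", "amide")) {
  n_term_mod <- match.arg(n_term_mod)
  c_term_mod <- match.arg(c_term_mod)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    ps_stop("sequence must be a non-empty character string", "input_error")
  seq <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!seq %in% AA1)
  if (length(bad) > 0L)
    ps_stop(sprintf("invalid amino-acid code '%s' at position %d",
                    seq[bad[1L]], bad[1L]), "alphabet_error")
  if (length(seq) < 2L)
    ps_stop("a peptide needs at least 2 residues", "input_error")
  start_number <- as.integer(start_number)
  numbers <- start_number + seq_along(seq) - 1L
  structure(list(
    name = as.character(name),
    sequence = seq,
    numbers = numbers,
    n_term_mod = n_term_mod,
    c_term_mod = c_term_mod,
    bw_labels = stats::setNames(character(0), character(0))
  ), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  caps <- paste0(if (x$n_term_mod == "acetyl") "Ac-" else "H-",
                 paste(x$sequence, collapse = ""),
                 if (x$c_term_mod == "amide") "-NH2" else "-OH")
  cat(sprintf("Peptide %s: %s\n", x$name, caps))
  cat(sprintf("  residues %d-%d (%d residues)\n",
              x$numbers[1L], x$numbers[length(x$numbers)], length(x$numbers)))
  if (length(x$bw_labels) > 0L)
    cat(sprintf("  %d Ballesteros-Weinstein labels\n", length(x$bw_labels)))
  invisible(x)
}

#' @export
length.peptide <- function(x) length(x$sequence)

#' Residue table of a peptide
#'
#' @param peptide A `peptide`.
#' @return A data frame with columns `number` (absolute), `code` (one-letter)
#'   and `bw_label` (`NA` where unlabelled).
#' @export
residue_ids <- function(peptide) {
  stopifnot(inherits(peptide, "peptide"))
  bw <- rep(NA_character_, length(peptide$sequence))
  if (length(peptide$bw_labels) > 0L) {
    idx <- match(as.integer(names(peptide$bw_labels)), peptide$numbers)
    bw[idx] <- unname(peptide$bw_labels)
  }
  data.frame(number = peptide$numbers, code = peptide$sequence,
             bw_label = bw, stringsAsFactors = FALSE)
}

#' One-letter code at an absolute residue number
#' @param peptide A `peptide`.
#' @param number Absolute residue number(s).
#' @return Character vector of one-letter codes.
#' @export
residue_code <- function(peptide, number) {
  idx <- match(as.integer(number), peptide$numbers)
  if (anyNA(idx))
    ps_stop(sprintf("residue %s not in peptide %s",
                    paste(number[is.na(idx)], collapse = ","), peptide$name),
            "mapping_error")
  peptide$sequence[idx]
}

#' Attach Ballesteros-Weinstein labels
#'
#' GPCR-generic position labels (helix.position) are supplied as
#' configuration, keyed by absolute residue number; residues not listed keep
#' an empty label. Labels are annotation only and never affect numerics.
#'
#' @param peptide A `peptide`.
#' @param mapping A list of `(absolute_number, label)` pairs, or a named
#'   character vector whose names are absolute residue numbers.
#' @return The labelled `peptide`.
#' @export
attach_bw_labels <- function(peptide, mapping) {
  stopifnot(inherits(peptide, "peptide"))
  if (length(mapping) == 0L) return(peptide)
  if (is.list(mapping)) {
    nums <- vapply(mapping, function(p) as.integer(p[[1L]]), integer(1))
    labs <- vapply(mapping, function(p) as.character(p[[2L]]), character(1))
  } else {
    nums <- as.integer(names(mapping))
    labs <- as.character(mapping)
  }
  bad <- setdiff(nums, peptide$numbers)
  if (length(bad) > 0L)
    ps_stop(sprintf("BW mapping refers to residue(s) %s outside peptide %s",
                    paste(bad, collapse = ","), peptide$name), "mapping_error")
  merged <- peptide$bw_labels
  merged[as.character(nums)] <- labs
  peptide$bw_labels <- merged
  peptide
}

#' Read / write a peptide definition file
#'
#' The definition file is a small JSON object with fields `name`,
#' `sequence`, `start_number`, `n_term_mod`, `c_term_mod` and an optional
#' `bw_labels` map from absolute residue number to label.
#'
#' @param path File path.
#' @return `read_peptide()` returns a `peptide`; `write_peptide()` returns
#'   `path` invisibly.
#' @export
read_peptide <- function(path) {
  if (!file.exists(path))
    ps_stop(sprintf("peptide definition file not found: %s", path), "io_error")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- parse_peptide(cfg$name, cfg$sequence, cfg$start_number,
                     n_term_mod = cfg$n_term_mod %||% "free",
                     c_term_mod = cfg$c_term_mod %||% "free")
  if (!is.null(cfg$bw_labels) && length(cfg$bw_labels) > 0L)
    p <- attach_bw_labels(p, unlist(cfg$bw_labels))
  p
}

#' @rdname read_peptide
#' @param peptide A `peptide` to serialise.
#' @export
write_peptide <- function(peptide, path) {
  stopifnot(inherits(peptide, "peptide"))
  obj <- list(
    name = peptide$name,
    sequence = paste(peptide$sequence, collapse = ""),
    start_number = peptide$numbers[1L],
    n_term_mod = peptide$n_term_mod,
    c_term_mod = peptide$c_term_mod
  )
  if (length(peptide$bw_labels) > 0L)
    obj$bw_labels <- as.list(peptide$bw_labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
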