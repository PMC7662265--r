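# Random-coil chemical-shift reference values.
#
# Secondary shifts are always differences against this table, so the same
# named set must be recorded in every profile derived from it; the set
# identifier travels with each delta_profile for provenance.

# Wishart-style random-coil shifts (ppm) for Halpha (HA), backbone amide
# proton (HN) and Calpha (CA), pH ~5, 25 C, as commonly tabulated for
# unstructured GGXGG-type peptides.
.rc_wishart1995 <- local({
  m <- rbind(
    #     HA    HN    CA
    A = c(4.32, 8.24, 52.5),
    C = c(4.55, 8.32, 58.2),
    D = c(4.64, 8.34, 54.2),
    E = c(4.35, 8.42, 56.6),
    F = c(4.62, 8.30, 57.7),
    G = c(3.96, 8.33, 45.1),
    H = c(4.73, 8.42, 55.0),
    I = c(4.17, 8.00, 61.1),
    K = c(4.32, 8.29, 56.2),
    L = c(4.34, 8.16, 55.1),
    M = c(4.48, 8.28, 55.4),
    N = c(4.74, 8.40, 53.1),
    P = c(4.42, NA,   63.3),   # Pro has no backbone amide proton
    Q = c(4.34, 8.32, 55.7),
    R = c(4.34, 8.23, 56.0),
    S = c(4.47, 8.31, 58.3),
    T = c(4.35, 8.15, 61.8),
    V = c(4.12, 8.03, 62.2),
    W = c(4.66, 8.25, 57.5),
    Y = c(4.55, 8.12, 57.9)
  )
  colnames(m) <- c("HA", "HN", "CA")
  m
})

#' Random-coil reference table
#'
#' Returns a named random-coil chemical-shift reference set, complete for
#' all 20 canonical amino acids for the HA and CA nuclei (HN is provided
#' for all residues except proline). The set identifier is stored in every
#' derived secondary-shift profile so results remain traceable to the
#' reference they were computed against.
#'
#' @param name Reference-set identifier; currently `"wishart1995"`
#'   (Wishart-style coil values for short unstructured peptides).
#' @param values Optional user-supplied replacement matrix (rows = one-letter
#'   amino-acid codes, columns `HA`, `HN`, `CA`), registered under `name`.
#' @return An object of class `random_coil_table` with fields `name` and
#'   `values`.
#' @export
random_coil_table <- function(name = "wishart1995", values = NULL) {
  if (is.null(values)) {
    values <- switch(name,
      wishart1995 = .rc_wishart1995,
      ps_stop(sprintf("unknown random-coil set '%s'", name), "parameter_error")
    )
  } else {
    values <- as.matrix(values)
    if (!all(c("HA", "CA") %in% colnames(values)) ||
        !all(AA1 %in% rownames(values)))
      ps_stop("random-coil table must cover all 20 amino acids for HA and CA",
              "parameter_error")
  }
  structure(list(name = name, values = values), class = "random_coil_table")
}

# delta_RC(aa, nucleus); NA for Pro HN
rc_shift <- function(rc, code, nucleus) {
  rc$values[cbind(code, rep_len(nucleus, length(code)))]
}

#' @export
print.random_coil_table <- function(x, ...) {
  cat(sprintf("Random-coil reference set '%s' (%d residues x %s)\n",
              x$name, nrow(x$values), paste(colnames(x$values), collapse = "/")))
  invisible(x)
}
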