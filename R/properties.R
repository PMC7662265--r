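# Design-stage physicochemical properties: theoretical mass of terminally
# capped peptides, net charge vs pH, and isoelectric point.

# IUPAC standard atomic weights (average) and monoisotopic masses
.ATOMIC <- list(
  average = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06),
  mono    = c(C = 12, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, S = 31.97207069)
)

# residue (= amino acid minus water) element formulas, columns C,H,N,O,S
.RESIDUE_FORMULA <- local({
  m <- rbind(
    A = c(3, 5, 1, 1, 0),  C = c(3, 5, 1, 1, 1),  D = c(4, 5, 1, 3, 0),
    E = c(5, 7, 1, 3, 0),  F = c(9, 9, 1, 1, 0),  G = c(2, 3, 1, 1, 0),
    H = c(6, 7, 3, 1, 0),  I = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
    L = c(6, 11, 1, 1, 0), M = c(5, 9, 1, 1, 1),  N = c(4, 6, 2, 2, 0),
    P = c(5, 7, 1, 1, 0),  Q = c(5, 8, 2, 2, 0),  R = c(6, 12, 4, 1, 0),
    S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  V = c(5, 9, 1, 1, 0),
    W = c(11, 10, 2, 1, 0), Y = c(9, 9, 1, 2, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

#' Theoretical mass of a (capped) peptide
#'
#' Sums residue element formulas plus one water, then applies the terminal
#' caps at the element level: N-terminal acetylation adds C2H2O
#' (+42.04 Da average), C-terminal amidation replaces OH by NH2 (net
#' -O +N +H, -0.98 Da average). Masses are computed from the element
#' formula with IUPAC atomic weights, on both the average and the
#' monoisotopic scale.
#'
#' @param peptide A `peptide`.
#' @return An object of class `mass_result`: `average_da`, `monoisotopic_da`,
#'   `formula` (named element-count vector).
#' @examples
#' cb1 <- parse_peptide("CB1", "TVNPIIYALRSKDLRHAFR", 391, "acetyl", "amide")
#' peptide_mass(cb1)  # ~2311.7 Da average
#' @export
peptide_mass <- function(peptide) {
  stopifnot(inherits(peptide, "peptide"))
  counts <- colSums(.RESIDUE_FORMULA[peptide$sequence, , drop = FALSE])
  counts["H"] <- counts["H"] + 2; counts["O"] <- counts["O"] + 1   # + water
  if (peptide$n_term_mod == "acetyl") {
    counts["C"] <- counts["C"] + 2; counts["H"] <- counts["H"] + 2
    counts["O"] <- counts["O"] + 1
  }
  if (peptide$c_term_mod == "amide") {
    counts["O"] <- counts["O"] - 1; counts["N"] <- counts["N"] + 1
    counts["H"] <- counts["H"] + 1
  }
  structure(list(
    average_da = sum(counts * .ATOMIC$average[names(counts)]),
    monoisotopic_da = sum(counts * .ATOMIC$mono[names(counts)]),
    formula = counts
  ), class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  f <- x$formula[x$formula > 0]
  cat(sprintf("Mass: %.2f Da average, %.2f Da monoisotopic (%s)\n",
              x$average_da, x$monoisotopic_da,
              paste0(names(f), f, collapse = "")))
  invisible(x)
}

# Side-chain and terminal pKa scales. `sign` +1 for groups positive when
# protonated (bases), -1 for groups negative when deprotonated (acids).
.PKA_SCALES <- list(
  emboss = list(
    side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
    n_term = 8.6, c_term = 3.6
  ),
  lehninger = list(
    side = c(C = 8.3, D = 3.65, E = 4.25, H = 6.0, K = 10.53, R = 12.48,
             Y = 10.07),
    n_term = 9.69, c_term = 2.34
  )
)
.BASIC_GROUPS <- c("H", "K", "R", "n_term")

#' Titration model for a peptide
#'
#' Builds the ionizable-group inventory of a peptide under a named pKa
#' scale. Terminal caps are honoured: an acetylated N-terminus and an
#' amidated C-terminus contribute no terminal charges.
#'
#' @param peptide A `peptide`.
#' @param scale `"emboss"` (default) or `"lehninger"`.
#' @param pka Optional named numeric vector overriding individual side-chain
#'   pKa values (names among C, D, E, H, K, R, Y, n_term, c_term).
#' @return An object of class `titration_model`: data frame `groups` with
#'   columns `group`, `pka`, `sign`.
#' @export
titration_model <- function(peptide, scale = c("emboss", "lehninger"),
                            pka = NULL) {
  stopifnot(inherits(peptide, "peptide"))
  scale <- match.arg(scale)
  sc <- .PKA_SCALES[[scale]]
  vals <- c(sc$side, n_term = sc$n_term, c_term = sc$c_term)
  if (!is.null(pka)) vals[names(pka)] <- pka
  grp <- character(0)
  if (peptide$n_term_mod == "free") grp <- c(grp, "n_term")
  if (peptide$c_term_mod == "free") grp <- c(grp, "c_term")
  grp <- c(grp, peptide$sequence[peptide$sequence %in% names(sc$side)])
  structure(list(
    groups = data.frame(group = grp, pka = unname(vals[grp]),
                        sign = ifelse(grp %in% .BASIC_GROUPS, 1, -1),
                        stringsAsFactors = FALSE),
    scale = scale
  ), class = "titration_model")
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: a basic group
#' contributes `+1/(1 + 10^(pH - pKa))`, an acidic group
#' `-1/(1 + 10^(pKa - pH))`.
#'
#' @param peptide A `peptide`.
#' @param pH pH value in (0, 14).
#' @param model Optional `titration_model`; built with defaults if omitted.
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(peptide, pH, model = NULL) {
  if (!is_scalar_number(pH) || pH <= 0 || pH >= 14)
    ps_stop("pH must lie in (0, 14)", "parameter_error")
  model <- model %||% titration_model(peptide)
  g <- model$groups
  if (nrow(g) == 0L) return(0)
  pos <- g$sign > 0
  sum(ifelse(pos, 1 / (1 + 10^(pH - g$pka)), -1 / (1 + 10^(g$pka - pH))))
}

#' Isoelectric point
#'
#' Bisection on [net_charge()] over pH in (0, 14) to 1e-4 pH units. The pI
#' is defined only when the peptide carries at least one basic and one
#' acidic group (otherwise the charge never crosses zero).
#'
#' @param peptide A `peptide`.
#' @param model Optional `titration_model`.
#' @return pI (pH units).
#' @export
isoelectric_point <- function(peptide, model = NULL) {
  model <- model %||% titration_model(peptide)
  g <- model$groups
  if (!any(g$sign > 0) || !any(g$sign < 0))
    ps_stop("pI undefined: peptide needs both basic and acidic groups",
            "undefined_pi_error")
  lo <- 1e-6; hi <- 14 - 1e-6
  f <- function(p) net_charge(peptide, p, model)
  if (f(lo) < 0 || f(hi) > 0)
    ps_stop("pI undefined: net charge does not change sign over (0, 14)",
            "undefined_pi_error")
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
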