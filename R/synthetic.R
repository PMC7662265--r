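# Synthetic-data generators with known ground truth: two-state helix-coil
# shift tables, perturbed "mixture" tables, two-basis CD spectra, and ideal
# hinged two-helix coordinate ensembles. Every generator is deterministic
# under the seed carried by its simulation_spec.

#' Simulation settings
#'
#' Holds the seed and noise levels shared by the generators. Defaults match
#' typical per-measurement chemical-shift uncertainties: 0.01 ppm for 1H
#' and 0.1 ppm for 13C; CD noise is off by default.
#'
#' @param seed Integer RNG seed.
#' @param noise_h_ppm Gaussian SD for 1H shifts (ppm).
#' @param noise_c_ppm Gaussian SD for 13C shifts (ppm).
#' @param cd_noise_mdeg Gaussian SD for raw CD ellipticity (millidegrees).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, noise_h_ppm = 0.01, noise_c_ppm = 0.1,
                            cd_noise_mdeg = 0) {
  if (noise_h_ppm < 0 || noise_c_ppm < 0 || cd_noise_mdeg < 0)
    ps_stop("noise levels must be non-negative", "parameter_error")
  structure(list(seed = as.integer(seed), noise_h_ppm = noise_h_ppm,
                 noise_c_ppm = noise_c_ppm, cd_noise_mdeg = cd_noise_mdeg),
            class = "simulation_spec")
}

#' Per-residue helix probability profile
#'
#' @param peptide A `peptide`.
#' @param f A single helix fraction in [0, 1] applied to every residue, or
#'   a vector with one value per residue.
#' @return An object of class `helix_profile` (values named by absolute
#'   residue number).
#' @export
helix_profile <- function(peptide, f) {
  stopifnot(inherits(peptide, "peptide"))
  n <- length(peptide$sequence)
  if (length(f) == 1L) f <- rep(f, n)
  if (length(f) != n)
    ps_stop("profile length must match the peptide", "input_error")
  if (any(f < 0 | f > 1))
    ps_stop("helix probabilities must lie in [0, 1]", "input_error")
  structure(list(values = stats::setNames(as.numeric(f), peptide$numbers),
                 peptide = peptide), class = "helix_profile")
}

#' Simulate a two-state helix-coil shift table
#'
#' Observed shifts follow the two-state model:
#' `delta_obs(i, nu) = delta_RC(aa_i, nu) + f_i * limit(nu) + N(0, noise)`,
#' with the full-helix limits of [helix_population()] for HA and CA. Amide
#' protons (HN) are generated at their coil value plus noise (no helix
#' dependence is modelled for HN) and are omitted for proline.
#'
#' @param peptide A `peptide`.
#' @param profile A `helix_profile` over the same peptide.
#' @param rc A `random_coil_table`.
#' @param spec A `simulation_spec` (seed and noise levels).
#' @param condition Condition label stored in the table.
#' @return A `shift_table`.
#' @export
simulate_shift_table <- function(peptide, profile, rc,
                                 spec = simulation_spec(),
                                 condition = "synthetic") {
  stopifnot(inherits(profile, "helix_profile"))
  if (!identical(as.integer(names(profile$values)), peptide$numbers))
    ps_stop("profile does not match the peptide", "input_error")
  set.seed(spec$seed)
  rows <- list()
  for (i in seq_along(peptide$numbers)) {
    num <- peptide$numbers[i]; code <- peptide$sequence[i]
    fi <- profile$values[i]
    for (nuc in NUCLEI) {
      if (nuc == "HN" && code == "P") next
      base <- rc_shift(rc, code, nuc)
      lim <- if (nuc %in% names(HELIX_LIMITS)) HELIX_LIMITS[[nuc]] else 0
      sdv <- if (nuc == "CA") spec$noise_c_ppm else spec$noise_h_ppm
      rows[[length(rows) + 1L]] <- data.frame(
        number = num, nucleus = nuc,
        ppm = base + fi * lim + if (sdv > 0) stats::rnorm(1, 0, sdv) else 0)
    }
  }
  shift_table(peptide, do.call(rbind, rows), condition = condition)
}

#' Simulate a mixture shift table with localized perturbations
#'
#' Produces the "mixture" counterpart of a free-peptide table: specified
#' per-residue offsets on (HA, HN, CA) are added on top of the free shifts,
#' plus fresh measurement noise. The injected ground-truth offsets are
#' stored in the result's `ground_truth` attribute, enabling exact recovery
#' checks of downstream CSP flagging.
#'
#' @param free A `shift_table` of the free peptide.
#' @param perturbed Named list: names are absolute residue numbers, values
#'   numeric length-3 vectors `(dHA, dHN, dCA)` in ppm.
#' @param spec A `simulation_spec`.
#' @return A `shift_table` with attribute `ground_truth`.
#' @export
simulate_mixture_perturbation <- function(free, perturbed = list(),
                                          spec = simulation_spec()) {
  stopifnot(inherits(free, "shift_table"))
  nums <- as.integer(names(perturbed))
  bad <- setdiff(nums, free$shifts$number)
  if (length(bad) > 0L)
    ps_stop(sprintf("perturbed residue(s) %s not in the free table",
                    paste(bad, collapse = ",")), "input_error")
  set.seed(spec$seed)
  s <- free$shifts
  for (k in seq_along(perturbed)) {
    off <- stats::setNames(as.numeric(perturbed[[k]]), NUCLEI)
    for (nuc in NUCLEI) {
      if (off[[nuc]] == 0) next
      hit <- s$number == nums[k] & s$nucleus == nuc
      if (!any(hit)) {
        ps_warn(sprintf("offset on missing nucleus %s of residue %d skipped",
                        nuc, nums[k]))
        next
      }
      s$ppm[hit] <- s$ppm[hit] + off[[nuc]]
    }
  }
  noise_sd <- ifelse(s$nucleus == "CA", spec$noise_c_ppm, spec$noise_h_ppm)
  if (any(noise_sd > 0))
    s$ppm <- s$ppm + stats::rnorm(nrow(s), 0, noise_sd)
  out <- shift_table(free$peptide, s,
                     condition = paste0(free$condition, "+mixture"),
                     temperature_C = free$temperature_C, pH = free$pH)
  attr(out, "ground_truth") <- perturbed
  out
}

# Smooth parametric CD basis curves, anchored at 222 nm to the coil (+3000)
# and full-helix (-36000) limits of the 222 nm estimator. Shapes carry the
# canonical features only: coil minimum near 197 nm; helix double minima at
# 208/222 nm with a positive band below 195 nm.
.cd_basis_helix <- function(wl) {
  h <- 1.6 * exp(-((wl - 191) / 4.5)^2) -
    1.0 * exp(-((wl - 208) / 5.5)^2) -
    0.95 * exp(-((wl - 222) / 6.0)^2)
  h222 <- 1.6 * exp(-((222 - 191) / 4.5)^2) -
    1.0 * exp(-((222 - 208) / 5.5)^2) - 0.95
  h * (-36000 / h222)
}

.cd_basis_coil <- function(wl) {
  cc <- 0.075 - exp(-((wl - 197) / 7)^2)
  c222 <- 0.075 - exp(-((222 - 197) / 7)^2)
  cc * (3000 / c222)
}

#' Simulate a two-basis CD spectrum
#'
#' `[theta](lambda) = f * B_helix(lambda) + (1 - f) * B_coil(lambda)` plus
#' optional Gaussian noise. At 222 nm the construction is exactly
#' consistent with the inversion performed by
#' [helix_fraction_from_ellipticity()] (coil +3000, full helix -36000
#' deg cm^2 dmol^-1), so a noise-free spectrum round-trips the prescribed
#' helix fraction. Instrument noise (in millidegrees) is converted to the
#' mean-residue molar scale assuming a 50 uM sample in a 1 mm cell.
#'
#' @param f_helix Helix fraction in [0, 1].
#' @param n_res Number of residues (used only to scale instrument noise).
#' @param spec A `simulation_spec`.
#' @param wavelengths Wavelength grid in nm (default 190-260 at 0.5 nm).
#' @return A `cd_spectrum` in molar-ellipticity units.
#' @export
simulate_cd_spectrum <- function(f_helix, n_res = 19L,
                                 spec = simulation_spec(),
                                 wavelengths = seq(190, 260, by = 0.5)) {
  if (!is_scalar_number(f_helix) || f_helix < 0 || f_helix > 1)
    ps_stop("f_helix must lie in [0, 1]", "input_error")
  y <- f_helix * .cd_basis_helix(wavelengths) +
    (1 - f_helix) * .cd_basis_coil(wavelengths)
  if (spec$cd_noise_mdeg > 0) {
    set.seed(spec$seed)
    scale <- 10 * 50e-6 * 0.1 * n_res    # mdeg -> deg cm^2 dmol^-1 divisor
    y <- y + stats::rnorm(length(y), 0, spec$cd_noise_mdeg / scale)
  }
  cd_spectrum(wavelengths, y, units = "molar_ellipticity",
              meta = list(f_helix = f_helix, n_res = n_res))
}

# --- ideal helix construction ------------------------------------------

# place a new atom given three previous positions, a bond length r (A),
# a bond angle theta (deg, at b-c-new) and a torsion tau (deg, a-b-c-new)
.place_atom <- function(a, b, c, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  c + bc * d[1] + m * d[2] + n * d[3]
}

# N/CA/C backbone of a chain built from phi/psi (deg) with standard bond
# geometry (N-CA 1.458, CA-C 1.525, C-N 1.329 A; trans peptide bonds)
.build_backbone <- function(numbers, phi, psi) {
  n <- length(numbers)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  coords <- matrix(NA_real_, nrow = 3L * n, ncol = 3L)
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- .place_atom(c(0, 1, 0), N, CA, 1.525, 111.2, -120)
  coords[1L, ] <- N; coords[2L, ] <- CA; coords[3L, ] <- C
  for (i in 2:n) {
    N2 <- .place_atom(N, CA, C, 1.329, 116.2, psi[i - 1L])
    CA2 <- .place_atom(CA, C, N2, 1.458, 121.7, 180)
    C2 <- .place_atom(C, N2, CA2, 1.525, 111.2, phi[i])
    coords[3L * i - 2L, ] <- N2; coords[3L * i - 1L, ] <- CA2
    coords[3L * i, ] <- C2
    N <- N2; CA <- CA2; C <- C2
  }
  data.frame(resno = rep(numbers, each = 3L),
             name = rep(c("N", "CA", "C"), n),
             element = rep(c("N", "C", "C"), n),
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             stringsAsFactors = FALSE)
}

#' Ideal alpha-helix backbone model
#'
#' Builds an N/CA/C backbone for the whole peptide from uniform phi/psi
#' dihedrals (default -57/-47 degrees, canonical alpha helix) and standard
#' bond geometry.
#'
#' @param peptide A `peptide`.
#' @param phi,psi Backbone dihedrals in degrees.
#' @return A `model3d`.
#' @export
ideal_helix_model <- function(peptide, phi = -57, psi = -47) {
  stopifnot(inherits(peptide, "peptide"))
  model3d(.build_backbone(peptide$numbers, phi, psi))
}

.rotation_about_axis <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2)); a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# shortest rotation carrying unit vector a onto unit vector b
.rotation_between <- function(a, b) {
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(axis^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)  # any perpendicular
    perp <- p - sum(p * a) * a
    return(.rotation_about_axis(perp, 180))
  }
  .rotation_about_axis(axis, atan2(s, cth) * 180 / pi)
}

.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Build a hinged two-helix ensemble at a prescribed inter-helix angle
#'
#' Constructs an ideal alpha-helical backbone for the whole peptide, then
#' rotates everything from the start of the second segment onwards about an
#' axis perpendicular to the first helix axis (pivoting at the first CA of
#' the second segment) so that the two N-to-C helix axes meet at the
#' prescribed angle. Each model then receives an independent random rigid
#' motion and, optionally, isotropic Gaussian coordinate jitter.
#'
#' @param peptide A `peptide`.
#' @param segA,segB Disjoint `helix_segment`s (A before B).
#' @param angle_deg Prescribed inter-helix angle in [0, 180] degrees.
#' @param n_models Number of conformers (default 20).
#' @param jitter_A Gaussian SD added to every coordinate (Angstrom).
#' @param seed RNG seed.
#' @return A `model_ensemble`; write it with [write_model_ensemble()].
#' @export
build_hinged_helix_ensemble <- function(peptide, segA, segB, angle_deg,
                                        n_models = 20L, jitter_A = 0,
                                        seed = 1L) {
  stopifnot(inherits(segA, "helix_segment"), inherits(segB, "helix_segment"))
  if (segA$last >= segB$first)
    ps_stop("segments must be disjoint with segA before segB", "input_error")
  if (angle_deg < 0 || angle_deg > 180)
    ps_stop("angle must lie in [0, 180] degrees", "input_error")
  base <- ideal_helix_model(peptide)
  axA <- fit_helix_axis(base, segA)$direction
  axB0 <- fit_helix_axis(base, segB)$direction
  # target direction for the second axis: exactly angle_deg away from the
  # first axis, tilted within the plane spanned by axA and a perpendicular
  e <- if (abs(axA[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(axA[2] * e[3] - axA[3] * e[2],
         axA[3] * e[1] - axA[1] * e[3],
         axA[1] * e[2] - axA[2] * e[1])
  u <- u / sqrt(sum(u^2))
  a <- angle_deg * pi / 180
  target <- cos(a) * axA + sin(a) * u
  R <- .rotation_between(axB0, target)
  pivot_i <- which(base$resno == segB$first & base$name == "CA")
  pivot <- as.numeric(base[pivot_i, c("x", "y", "z")])
  xyz <- as.matrix(base[, c("x", "y", "z")])
  move <- base$resno >= segB$first
  xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2L, pivot) %*% t(R),
                       2L, pivot, `+`)
  set.seed(seed)
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    Rg <- .random_rotation()
    tg <- stats::rnorm(3, 0, 5)
    pts <- xyz %*% t(Rg) + matrix(tg, nrow(xyz), 3L, byrow = TRUE)
    if (jitter_A > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_A), nrow(pts), 3L)
    mod <- base
    mod$x <- pts[, 1L]; mod$y <- pts[, 2L]; mod$z <- pts[, 3L]
    models[[m]] <- model3d(mod)
  }
  model_ensemble(models, peptide)
}
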