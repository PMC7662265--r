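# Multi-model coordinate ensembles: PDB I/O, least-squares backbone
# superposition, helix-axis fitting, inter-helix angle statistics and a
# coarse Ramachandran summary.

BACKBONE <- c("N", "CA", "C")

#' Construct a single coordinate model
#'
#' @param atoms Data frame with columns `resno` (absolute residue number),
#'   `name` (atom name, e.g. `"CA"`), `element`, `x`, `y`, `z` (Angstrom).
#' @return An object of class `model3d` (a validated data frame).
#' @export
model3d <- function(atoms) {
  need <- c("resno", "name", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    ps_stop("atoms must have columns resno, name, element, x, y, z",
            "input_error")
  atoms <- as.data.frame(atoms)[, need]
  atoms$resno <- as.integer(atoms$resno)
  for (res in unique(atoms$resno)) {
    have <- atoms$name[atoms$resno == res]
    if (!all(BACKBONE %in% have))
      ps_stop(sprintf("residue %d lacks a complete N/CA/C backbone", res),
              "input_error")
  }
  class(atoms) <- c("model3d", "data.frame")
  atoms
}

#' Construct a model ensemble
#'
#' @param models List of `model3d` objects sharing atom count and naming.
#' @param peptide The `peptide` the coordinates describe.
#' @return An object of class `model_ensemble`.
#' @export
model_ensemble <- function(models, peptide) {
  stopifnot(length(models) >= 1L, inherits(peptide, "peptide"))
  ref <- models[[1L]]
  for (m in models) {
    if (nrow(m) != nrow(ref) || !identical(m$resno, ref$resno) ||
        !identical(m$name, ref$name))
      ps_stop("all models must share atom count and naming",
              "consistency_error")
  }
  out <- setdiff(unique(ref$resno), peptide$numbers)
  if (length(out) > 0L)
    ps_stop(sprintf("model residue number(s) %s not in peptide %s",
                    paste(sort(out), collapse = ","), peptide$name),
            "reconciliation_error")
  structure(list(models = models, peptide = peptide),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d model(s), %d atoms each, peptide %s\n",
              length(x$models), nrow(x$models[[1L]]), x$peptide$name))
  invisible(x)
}

#' @export
length.model_ensemble <- function(x) length(x$models)

#' Read a (multi-model) PDB file as an ensemble
#'
#' Honours ATOM / MODEL / ENDMDL / TER records only; alternate locations
#' other than blank or 'A' are rejected; occupancies are ignored. Residue
#' numbering must already match the peptide's absolute numbers.
#'
#' @param path PDB file (MODEL/ENDMDL delimit conformers; a single-model
#'   file yields an ensemble of one).
#' @param peptide The `peptide` to reconcile numbering against.
#' @return A `model_ensemble`.
#' @export
read_model_ensemble <- function(path, peptide) {
  if (!file.exists(path))
    ps_stop(sprintf("PDB file not found: %s", path), "io_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e)
      ps_stop(sprintf("failed to parse PDB (%s)", conditionMessage(e)),
              "consistency_error"))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  alt <- at$alt
  if (any(!is.na(alt) & !alt %in% c("", "A")))
    ps_stop("alternate locations other than blank/'A' are not supported",
            "consistency_error")
  xyz <- pdb$xyz                     # one row per model
  n_models <- nrow(xyz)
  keep <- which(pdb$atom$type == "ATOM")
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    coords <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    models[[m]] <- model3d(data.frame(
      resno = at$resno, name = at$elety,
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(at$elety, 1L, 1L), at$elesy),
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE))
  }
  model_ensemble(models, peptide)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble A `model_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  pep <- ensemble$peptide
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(ensemble$models) > 1L
  for (m in seq_along(ensemble$models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    at <- ensemble$models[[m]]
    res3 <- AA1TO3[residue_code(pep, at$resno)]
    nm <- ifelse(nchar(at$name) < 4L, sprintf(" %-3s", at$name), at$name)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), nm, res3, at$resno, at$x, at$y, at$z, 1, 0,
      at$element), con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# coordinates of a named-atom selection as an N x 3 matrix keyed by
# (resno, name); rows follow `key` order
.coords_for <- function(model, key) {
  idx <- match(key, paste(model$resno, model$name))
  cbind(model$x, model$y, model$z)[idx, , drop = FALSE]
}

#' Optimal least-squares superposition of two models
#'
#' Pairs atoms 1:1 by (residue number, atom name) over `selection`, then
#' finds the proper rigid motion (rotation with determinant +1 plus
#' translation) minimising the RMSD of the mobile atoms onto the reference
#' (Kabsch algorithm via SVD).
#'
#' @param reference,mobile `model3d` objects.
#' @param selection Atom names used for the fit (default backbone N, CA, C).
#' @return List with `rmsd` (Angstrom), `rotation` (3x3, det +1),
#'   `translation` (length-3), such that aligned mobile coordinates are
#'   `coords %*% t(rotation) + translation`.
#' @export
superpose_rmsd <- function(reference, mobile, selection = BACKBONE) {
  key_r <- paste(reference$resno, reference$name)
  key_m <- paste(mobile$resno, mobile$name)
  sel_r <- key_r[reference$name %in% selection]
  key <- intersect(sel_r, key_m[mobile$name %in% selection])
  if (length(key) < 3L)
    ps_stop("need at least 3 paired atoms for superposition",
            "degeneracy_error")
  A <- .coords_for(reference, key)
  B <- .coords_for(mobile, key)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- crossprod(B0, A0)             # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Bfit - A0)^2)))
  list(rmsd = rmsd, rotation = R,
       translation = as.numeric(ca - cb %*% t(R)))
}

#' Pairwise backbone RMSD matrix of an ensemble
#'
#' @param ensemble A `model_ensemble`.
#' @param selection Atom names used (default N, CA, C).
#' @return Symmetric matrix of superposition RMSDs (Angstrom).
#' @export
rmsd_matrix <- function(ensemble, selection = BACKBONE) {
  n <- length(ensemble$models)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    M[i, j] <- M[j, i] <-
      superpose_rmsd(ensemble$models[[i]], ensemble$models[[j]],
                     selection)$rmsd
  }
  M
}

#' Fit a helix axis through a segment's CA trace
#'
#' The axis is the dominant principal axis of the centred CA coordinates of
#' the segment, with its sign fixed so the projection of (last CA - first
#' CA) onto the axis is positive, i.e. the axis points N-terminus to
#' C-terminus. `rms_to_axis` (RMS distance of the CAs to the fitted line)
#' exposes fit quality.
#'
#' @param model A `model3d`.
#' @param segment A `helix_segment` with at least 4 CA atoms in the model.
#' @return An object of class `helix_axis`: unit `direction`, `centroid`,
#'   `segment`, `rms_to_axis`.
#' @export
fit_helix_axis <- function(model, segment) {
  stopifnot(inherits(segment, "helix_segment"))
  sel <- model$resno >= segment$first & model$resno <= segment$last &
    model$name == "CA"
  X <- cbind(model$x, model$y, model$z)[sel, , drop = FALSE]
  X <- X[order(model$resno[sel]), , drop = FALSE]
  if (nrow(X) < 4L)
    ps_stop(sprintf("segment %s has fewer than 4 CA atoms", format(segment)),
            "degeneracy_error")
  ctr <- colMeans(X)
  X0 <- sweep(X, 2L, ctr)
  v <- svd(X0)$v[, 1L]
  if (sum((X[nrow(X), ] - X[1L, ]) * v) < 0) v <- -v
  proj <- X0 %*% v
  perp2 <- rowSums(X0^2) - proj^2
  structure(list(direction = as.numeric(v / sqrt(sum(v^2))),
                 centroid = as.numeric(ctr), segment = segment,
                 rms_to_axis = sqrt(mean(pmax(perp2, 0)))),
            class = "helix_axis")
}

#' Inter-helix angle statistics over an ensemble
#'
#' For each model, fits N-to-C-directed axes through the two segments and
#' takes `acos(dirA . dirB)` in degrees. Because the axes are directed,
#' the angle lives in [0, 180] and obtuse inter-helix angles are
#' meaningful (parallel = 0, antiparallel = 180).
#'
#' @param ensemble A `model_ensemble`.
#' @param segA,segB `helix_segment` objects present in every model.
#' @return List with `angles` (per model, degrees), `mean`, `sd`.
#' @export
interhelix_angle <- function(ensemble, segA, segB) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  ang <- vapply(ensemble$models, function(m) {
    a <- fit_helix_axis(m, segA)$direction
    b <- fit_helix_axis(m, segB)$direction
    acos(max(-1, min(1, sum(a * b)))) * 180 / pi
  }, numeric(1))
  list(angles = ang, mean = mean(ang),
       sd = if (length(ang) > 1L) stats::sd(ang) else 0)
}

# dihedral angle (degrees, in (-180, 180]) of four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# coarse rectangular phi/psi regions; "favored" covers the alpha, beta and
# left-handed-alpha cores, "allowed" a 20-degree margin around each
.rama_region <- function(phi, psi) {
  inside <- function(p, q, box) p > box[1] && p < box[2] && q > box[3] && q < box[4]
  favored <- list(alpha = c(-160, -20, -90, 10),
                  beta  = c(-180, -20, 90, 180),
                  Lalpha = c(20, 90, -10, 90))
  for (b in favored) if (inside(phi, psi, b)) return("favored")
  for (b in favored) {
    eb <- b + c(-20, 20, -20, 20)
    if (inside(phi, psi, eb)) return("allowed")
  }
  "outlier"
}

#' Coarse Ramachandran summary of an ensemble
#'
#' Computes backbone phi/psi for every interior residue of every model and
#' classifies each pair into coarse rectangular favored / allowed / outlier
#' regions (alpha, beta and left-handed-alpha cores plus a 20-degree
#' margin). Residues adjacent to a chain break are skipped with a warning.
#'
#' @param ensemble A `model_ensemble`.
#' @return List with `fractions` (named, summing to 1 over evaluable
#'   residues) and `table` (per model/residue phi, psi, region).
#' @export
ramachandran_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  rows <- list()
  skipped <- 0L
  for (m in seq_along(ensemble$models)) {
    mod <- ensemble$models[[m]]
    resnos <- sort(unique(mod$resno))
    get <- function(res, name) {
      i <- which(mod$resno == res & mod$name == name)[1L]
      if (is.na(i)) NULL else c(mod$x[i], mod$y[i], mod$z[i])
    }
    for (k in seq_along(resnos)) {
      res <- resnos[k]
      if (k == 1L || k == length(resnos)) next
      if (resnos[k - 1L] != res - 1L || resnos[k + 1L] != res + 1L) {
        skipped <- skipped + 1L
        next
      }
      cm <- get(res - 1L, "C"); n <- get(res, "N"); ca <- get(res, "CA")
      cc <- get(res, "C"); np <- get(res + 1L, "N")
      phi <- .dihedral(cm, n, ca, cc)
      psi <- .dihedral(n, ca, cc, np)
      rows[[length(rows) + 1L]] <-
        data.frame(model = m, resno = res, phi = phi, psi = psi,
                   region = .rama_region(phi, psi))
    }
  }
  if (skipped > 0L)
    ps_warn(sprintf("%d residue(s) skipped at chain breaks", skipped))
  if (length(rows) == 0L)
    ps_stop("no evaluable residues for Ramachandran analysis", "input_error")
  tab <- do.call(rbind, rows)
  fr <- table(factor(tab$region, levels = c("favored", "allowed", "outlier")))
  list(fractions = stats::setNames(as.numeric(fr) / nrow(tab), names(fr)),
       table = tab)
}
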