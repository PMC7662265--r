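segA <- helix_segment(394, 402)
segB <- helix_segment(404, 408)

test_that("multi-model PDB files round-trip through the ensemble reader", {
  cb1 <- cb1_peptide()
  ens <- build_hinged_helix_ensemble(cb1, segA, segB, 90, n_models = 20,
                                     jitter_A = 0, seed = 2)
  expect_equal(length(ens), 20L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_ensemble(ens, path)
  back <- read_model_ensemble(path, cb1)
  expect_equal(length(back), 20L)
  for (m in c(1L, 10L, 20L)) {
    expect_identical(back$models[[m]]$resno, ens$models[[m]]$resno)
    expect_identical(back$models[[m]]$name, ens$models[[m]]$name)
    expect_equal(as.matrix(back$models[[m]][, c("x", "y", "z")]),
                 as.matrix(ens$models[[m]][, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  # geometry is preserved to coordinate-precision after the round trip
  a0 <- interhelix_angle(ens, segA, segB)$mean
  a1 <- interhelix_angle(back, segA, segB)$mean
  expect_equal(a1, a0, tolerance = 0.1)
})

test_that("single-model files parse and shifted numbering is rejected", {
  cb1 <- cb1_peptide()
  one <- build_hinged_helix_ensemble(cb1, segA, segB, 45, n_models = 1,
                                     jitter_A = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_ensemble(one, path)
  back <- read_model_ensemble(path, cb1)
  expect_equal(length(back), 1L)

  shifted <- parse_peptide("shifted", "TVNPIIYALRSKDLRHAFR", 491)
  expect_error(read_model_ensemble(path, shifted),
               class = "reconciliation_error")
})

test_that("superposition is exact for identical and rigidly moved models", {
  cb1 <- cb1_peptide()
  m <- build_hinged_helix_ensemble(cb1, segA, segB, 94, n_models = 1,
                                   jitter_A = 0, seed = 1)$models[[1]]
  fit <- superpose_rmsd(m, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  set.seed(3)
  moved <- apply_rigid(m, random_rigid_motion())
  fit2 <- superpose_rmsd(m, moved)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  # returned motion actually aligns the mobile coordinates
  aligned <- as.matrix(moved[, c("x", "y", "z")]) %*% t(fit2$rotation) +
    matrix(fit2$translation, nrow(moved), 3, byrow = TRUE)
  expect_equal(aligned, as.matrix(m[, c("x", "y", "z")]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("superposition RMSD is symmetric and needs 3 pairs", {
  cb1 <- cb1_peptide()
  set.seed(8)
  ens <- build_hinged_helix_ensemble(cb1, segA, segB, 75, n_models = 2,
                                     jitter_A = 0.5, seed = 8)
  a <- superpose_rmsd(ens$models[[1]], ens$models[[2]])$rmsd
  b <- superpose_rmsd(ens$models[[2]], ens$models[[1]])$rmsd
  expect_equal(a, b, tolerance = 1e-9)

  tiny <- model3d(data.frame(resno = 1, name = c("N", "CA", "C"),
                             element = c("N", "C", "C"),
                             x = c(0, 1.4, 2), y = c(0, 0, 1), z = 0))
  expect_error(superpose_rmsd(tiny, tiny, selection = "CA"),
               class = "degeneracy_error")
})

test_that("superposition matches a quaternion-search oracle", {
  set.seed(17)
  for (trial in 1:10) {
    A <- matrix(rnorm(30, sd = 3), 10, 3)
    B <- matrix(rnorm(30, sd = 3), 10, 3)
    # give every residue a backbone by colocating N and C with CA
    full <- function(M) {
      df <- do.call(rbind, lapply(1:10, function(i) data.frame(
        resno = i, name = c("N", "CA", "C"), element = c("N", "C", "C"),
        x = M[i, 1], y = M[i, 2], z = M[i, 3])))
      model3d(df)
    }
    got <- superpose_rmsd(full(A), full(B), selection = "CA")$rmsd
    want <- oracle_superpose_rmsd(A, B)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("helix-axis fit recovers construction, orientation and rotation", {
  cb1 <- cb1_peptide()
  base <- ideal_helix_model(cb1)
  ax <- fit_helix_axis(base, segA)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
  expect_lt(ax$rms_to_axis, 2.5)    # CAs wind around the axis at ~2.3 A

  # align the helix with +z, then check direction and N->C orientation
  R <- diag(3)
  z <- c(0, 0, 1)
  v <- ax$direction
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  ang <- atan2(sqrt(sum(axis^2)), sum(v * z))
  if (sum(axis^2) > 1e-12) {
    u <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  rot <- apply_rigid(base, list(R = R, t = c(0, 0, 0)))
  expect_equal(fit_helix_axis(rot, segA)$direction, z, tolerance = 1e-6)

  # reversing the chain flips the N->C direction: use a window mapped onto
  # itself by the renumbering so the fitted point set is identical
  rev_model <- rot
  rev_model$resno <- max(rot$resno) + min(rot$resno) - rot$resno
  mid <- helix_segment(396, 404)      # 396 + 404 = 391 + 409
  fwd <- fit_helix_axis(rot, mid)$direction
  expect_equal(fit_helix_axis(rev_model, mid)$direction, -fwd,
               tolerance = 1e-9)

  # equivariance under a known rotation
  set.seed(9)
  motion <- random_rigid_motion()
  moved <- apply_rigid(rot, motion)
  expect_equal(fit_helix_axis(moved, segA)$direction,
               as.numeric(motion$R %*% z), tolerance = 1e-6)

  expect_error(fit_helix_axis(base, helix_segment(391, 393)),
               class = "degeneracy_error")
})

test_that("inter-helix angles: construction, limits, rigid invariance", {
  cb1 <- cb1_peptide()
  ens94 <- build_hinged_helix_ensemble(cb1, segA, segB, 94, n_models = 5,
                                       jitter_A = 0, seed = 4)
  expect_equal(interhelix_angle(ens94, segA, segB)$mean, 94, tolerance = 2)

  # two copies of one identical helix in a single model: a translated copy
  # is exactly parallel (0 deg); a copy rotated 180 deg about an axis
  # perpendicular to the helix is exactly antiparallel (180 deg)
  base <- ideal_helix_model(cb1)
  segN <- helix_segment(391, 399)
  first <- base[base$resno <= 399, ]
  copy_at <- function(xyz_fun) {
    cp <- first
    M <- xyz_fun(as.matrix(cp[, c("x", "y", "z")]))
    cp$x <- M[, 1]; cp$y <- M[, 2]; cp$z <- M[, 3]
    cp$resno <- cp$resno + 10L          # becomes residues 401-409
    model3d(rbind(first, cp))
  }
  par_model <- copy_at(function(M) sweep(M, 2, c(25, 0, 0), `+`))
  segC <- helix_segment(401, 409)
  expect_equal(interhelix_angle(model_ensemble(list(par_model), cb1),
                                segN, segC)$mean, 0, tolerance = 1e-6)

  dirN <- fit_helix_axis(base, segN)$direction
  perp <- c(-dirN[2], dirN[1], 0)      # perpendicular to dirN
  if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  ang <- pi
  K <- matrix(c(0, perp[3], -perp[2], -perp[3], 0, perp[1],
                perp[2], -perp[1], 0), 3, 3)
  R180 <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  anti_model <- copy_at(function(M) M %*% t(R180) +
                          matrix(c(25, 0, 0), nrow(M), 3, byrow = TRUE))
  expect_equal(interhelix_angle(model_ensemble(list(anti_model), cb1),
                                segN, segC)$mean, 180, tolerance = 1e-6)

  # invariant under a global rigid motion of every model
  set.seed(21)
  motion <- random_rigid_motion()
  moved <- model_ensemble(lapply(ens94$models, apply_rigid, motion), cb1)
  expect_equal(interhelix_angle(moved, segA, segB)$angles,
               interhelix_angle(ens94, segA, segB)$angles, tolerance = 1e-6)
})

test_that("prescribed hinge angles are recovered under coordinate jitter", {
  cb1 <- cb1_peptide()
  for (ang in c(45, 94)) {
    ens <- build_hinged_helix_ensemble(cb1, segA, segB, ang, n_models = 20,
                                       jitter_A = 0.2, seed = 100 + ang)
    expect_equal(interhelix_angle(ens, segA, segB)$mean, ang, tolerance = 3)
  }
})

test_that("Ramachandran summary classifies helical and extended dihedrals", {
  cb1 <- cb1_peptide()
  helix <- model_ensemble(list(ideal_helix_model(cb1)), cb1)
  rs <- ramachandran_summary(helix)
  expect_equal(unname(rs$fractions["favored"]), 1.0)
  expect_equal(sum(rs$fractions), 1.0)

  # phi/psi = (+150, +150) is far outside every favored core
  odd <- model_ensemble(list(ideal_helix_model(cb1, phi = 150, psi = 150)),
                        cb1)
  ro <- ramachandran_summary(odd)
  expect_equal(unname(ro$fractions["favored"]), 0.0)

  tiny <- model3d(data.frame(resno = rep(1:2, each = 3),
                             name = rep(c("N", "CA", "C"), 2),
                             element = rep(c("N", "C", "C"), 2),
                             x = rnorm(6), y = rnorm(6), z = rnorm(6)))
  pep2 <- parse_peptide("di", "AA", 1)
  expect_error(ramachandran_summary(model_ensemble(list(tiny), pep2)),
               class = "input_error")
})

test_that("pairwise RMSD matrix is symmetric with a zero diagonal", {
  cb1 <- cb1_peptide()
  ens <- build_hinged_helix_ensemble(cb1, segA, segB, 94, n_models = 4,
                                     jitter_A = 0.3, seed = 6)
  M <- rmsd_matrix(ens)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4))
  expect_true(all(M[upper.tri(M)] > 0))
})
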