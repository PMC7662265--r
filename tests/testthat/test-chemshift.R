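rc <- random_coil_table()

test_that("shift tables validate residues, nuclei, duplicates and ranges", {
  cb1 <- cb1_peptide()
  ok <- make_shift_table(cb1, c(391, 391, 392), c("HA", "CA", "HA"),
                         c(4.3, 60.2, 4.1))
  expect_s3_class(ok, "shift_table")

  expect_error(make_shift_table(cb1, 999, "HA", 4.3),
               class = "reconciliation_error")
  expect_error(make_shift_table(cb1, c(391, 391), c("HA", "HA"), c(4.3, 4.4)),
               class = "format_error")
  # residue 394 of CB1 is proline: no amide proton
  expect_error(make_shift_table(cb1, 394, "HN", 8.2), class = "format_error")
  expect_error(make_shift_table(cb1, 391, "HA", 15), class = "format_error")
  expect_error(make_shift_table(cb1, 391, "CA", 5), class = "format_error")
  expect_error(make_shift_table(cb1, 391, "XX", 4.3), class = "format_error")
})

test_that("csv and NMR-STAR readers give identical tables on one fixture", {
  pep <- parse_peptide("mini", "ADL", 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_number,residue_code,nucleus,shift_ppm",
               "1,A,HA,4.25", "1,A,CA,52.9", "2,D,HA,4.60",
               "2,D,CA,54.5", "3,L,HA,4.30", "3,L,CA,55.4"), csv)
  t_csv <- read_shift_table(csv, pep, format = "csv")
  expect_equal(nrow(t_csv$shifts), 6L)

  star <- withr::local_tempfile(fileext = ".str")
  write_shift_table(t_csv, star, format = "nmrstar")
  t_star <- read_shift_table(star, pep, format = "nmrstar")
  expect_equal(t_star$shifts, t_csv$shifts, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_number,residue_code,nucleus,shift_ppm",
               "999,A,HA,4.25"), bad)
  expect_error(read_shift_table(bad, pep), class = "reconciliation_error")

  mism <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_number,residue_code,nucleus,shift_ppm",
               "1,G,HA,4.25"), mism)
  expect_error(read_shift_table(mism, pep), class = "reconciliation_error")
})

test_that("NMR-STAR reader ignores unsupported atoms with a message", {
  pep <- parse_peptide("mini", "ADL", 1)
  star <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_x", "loop_",
               "  _Atom_chem_shift.Seq_ID",
               "  _Atom_chem_shift.Comp_ID",
               "  _Atom_chem_shift.Atom_ID",
               "  _Atom_chem_shift.Val",
               "  1 ALA HA 4.25", "  1 ALA HB 1.39", "  2 ASP CB 41.1",
               "  2 ASP CA 54.5", "  3 LEU H 8.10",
               "stop_"), star)
  expect_message(tab <- read_shift_table(star, pep, format = "nmrstar"),
                 "ignored 2")
  expect_equal(nrow(tab$shifts), 3L)
  expect_equal(observed_shift(tab, 3, "HN"), 8.10)
})

test_that("secondary shifts subtract the reference and are invertible", {
  cb1 <- cb1_peptide()
  # table sitting exactly at random-coil values -> all-zero profile
  tab0 <- simulate_shift_table(cb1, helix_profile(cb1, 0), rc,
                               simulation_spec(1, 0, 0))
  prof0 <- secondary_shifts(tab0, rc, "HA")
  expect_equal(unname(prof0$values), rep(0, 19))

  # exact inversion: delta_RC + delta reproduces delta_obs
  set.seed(7)
  tab <- simulate_shift_table(cb1, helix_profile(cb1, runif(19)), rc,
                              simulation_spec(7))
  for (nuc in c("HA", "CA")) {
    pr <- secondary_shifts(tab, rc, nuc)
    nums <- as.integer(names(pr$values))
    obs <- vapply(nums, function(n) observed_shift(tab, n, nuc), numeric(1))
    ref <- vapply(nums, function(n)
      rc$values[residue_code(cb1, n), nuc], numeric(1))
    expect_equal(ref + unname(pr$values), obs, tolerance = 1e-12)
  }

  expect_error(secondary_shifts(tab, rc, "HN"), class = "unsupported_error")
  expect_equal(prof0$source$rc_set, "wishart1995")
})

test_that("missing residues are absent from profiles, never zero-filled", {
  pep <- parse_peptide("mini", "ADLGK", 1)
  tab <- make_shift_table(pep, c(1, 2, 4), rep("HA", 3), c(4.1, 4.2, 3.8))
  pr <- secondary_shifts(tab, rc, "HA")
  expect_setequal(names(pr$values), c("1", "2", "4"))
})

test_that("full-helix synthetic tables hit the limiting secondary shifts", {
  cb1 <- cb1_peptide()
  tab <- simulate_shift_table(cb1, helix_profile(cb1, 1), rc,
                              simulation_spec(1, 0, 0))
  expect_equal(unname(secondary_shifts(tab, rc, "HA")$values),
               rep(-0.39, 19), tolerance = 1e-12)
  expect_equal(unname(secondary_shifts(tab, rc, "CA")$values),
               rep(3.1, 19), tolerance = 1e-12)
})

test_that("segment detection reproduces the two-helix/breaker decomposition", {
  cb1 <- cb1_peptide()
  # profile negative below the coil band at 394-402 and 404-408, positive at
  # the 403 breaker, coil-like elsewhere
  vals <- stats::setNames(rep(0.0, 19), 391:409)
  vals[as.character(394:402)] <- -0.25
  vals[as.character(404:408)] <- -0.15
  vals["403"] <- +0.08
  prof <- structure(list(nucleus = "HA", values = vals, peptide = cb1,
                         source = list(condition = "TFE-like", rc_set = "x")),
                    class = "delta_profile")
  segs <- detect_helical_segments(prof)
  expect_equal(segs_to_pairs(segs), list(c(394, 402), c(404, 408)))
})

test_that("segment detection handles degenerate profiles", {
  cb1 <- cb1_peptide()
  mk <- function(vals) structure(
    list(nucleus = "HA", values = vals, peptide = cb1,
         source = list(condition = "x", rc_set = "x")),
    class = "delta_profile")
  expect_equal(detect_helical_segments(mk(stats::setNames(numeric(0),
                                                          character(0)))),
               list())
  expect_equal(detect_helical_segments(
    mk(stats::setNames(rep(0, 19), 391:409))), list())
  alt <- stats::setNames(rep(c(-0.2, 0.2), length.out = 19), 391:409)
  expect_equal(detect_helical_segments(mk(alt)), list())
})

test_that("segment detection agrees with brute-force run enumeration", {
  cb1 <- cb1_peptide()
  set.seed(11)
  for (trial in 1:300) {
    L <- sample(5:25, 1)
    nums <- sort(sample(1:25, L))
    vals <- stats::setNames(round(rnorm(L, 0, 0.15), 3), nums)
    pep <- parse_peptide("r", paste(rep("A", 25), collapse = ""), 1)
    prof <- structure(list(nucleus = "HA", values = vals, peptide = pep,
                           source = list(condition = "x", rc_set = "x")),
                      class = "delta_profile")
    got <- segs_to_pairs(detect_helical_segments(prof))
    want <- oracle_segments(vals)
    expect_identical(got, want)
  }
})

test_that("segment averages are plain means over residues present", {
  pep <- parse_peptide("mini", "ADL", 1)
  mk <- function(vals) structure(
    list(nucleus = "HA", values = vals, peptide = pep,
         source = list(condition = "x", rc_set = "x")),
    class = "delta_profile")
  seg <- helix_segment(1, 3)
  expect_equal(segment_average(mk(c(`1` = -0.2, `2` = -0.3, `3` = -0.1)), seg),
               -0.2)
  expect_equal(segment_average(mk(c(`1` = -0.2, `3` = -0.1)), seg), -0.15)
  expect_equal(segment_average(mk(c(`1` = -0.2, `2` = -0.2, `3` = -0.2)), seg),
               -0.2)
  expect_error(segment_average(mk(c(`1` = -0.2)), helix_segment(2, 3)),
               class = "empty_segment_error")
})

test_that("two-state conversion reproduces the tabulated populations", {
  expect_equal(helix_population(-0.24, "HA")$rounded, 62)
  expect_equal(helix_population(+2.50, "CA")$rounded, 81)
  expect_equal(helix_population(0, "HA")$percent, 0)
  # propagated errors: 100 * measurement error / |limit|
  expect_equal(helix_population(-0.2, "HA")$error_percent, 100 * 0.01 / 0.39,
               tolerance = 1e-9)
  expect_equal(helix_population(2, "CA")$error_percent, 100 * 0.1 / 3.1,
               tolerance = 1e-9)
  expect_true(helix_population(-0.5, "HA")$range_warning)
  expect_error(helix_population(-0.2, "HA", limits = c(HA = 0, CA = 3.1)),
               class = "parameter_error")
})

test_that("more negative average HA shifts give strictly larger populations", {
  avgs <- seq(-0.05, -0.39, by = -0.02)
  pops <- vapply(avgs, function(a) helix_population(a, "HA")$percent,
                 numeric(1))
  expect_true(all(diff(pops) > 0))
})

test_that("combining HA and CA populations averages the rounded pair", {
  seg <- helix_segment(404, 408)
  # construct estimates whose rounded percentages are exactly 37 and 49
  p_ha <- helix_population(0.37 * -0.39, "HA", segment = seg)
  p_ca <- helix_population(0.49 * 3.1, "CA", segment = seg)
  expect_equal(p_ha$rounded, 37)
  expect_equal(p_ca$rounded, 49)
  comb <- combine_populations(p_ha, p_ca)
  expect_equal(comb$percent, 43)
  expect_equal(comb$error_percent, 6)
  expect_equal(comb$nucleus, "combined")

  p1 <- helix_population(0.22 * -0.39, "HA", segment = seg)
  p2 <- helix_population(0.16 * 3.1, "CA", segment = seg)
  c2 <- combine_populations(p1, p2)
  expect_equal(c2$percent, 19)
  expect_equal(c2$error_percent, 3)

  same <- combine_populations(p1, p1)
  expect_equal(same$percent, p1$rounded)
  expect_equal(same$error_percent, 0)

  other <- helix_population(0.2, "CA", segment = helix_segment(394, 402))
  expect_error(combine_populations(p_ha, other), class = "pairing_error")
})

test_that("populations recover the simulated helix fraction within tolerance", {
  cb1 <- cb1_peptide()
  seg <- helix_segment(391, 409)
  for (f in c(0.2, 0.5, 0.8)) {
    ok_ha <- 0L; ok_ca <- 0L
    n_rep <- 200L
    for (r in seq_len(n_rep)) {
      tab <- simulate_shift_table(cb1, helix_profile(cb1, f), rc,
                                  simulation_spec(seed = 1000 * f + r))
      p_ha <- helix_population(
        segment_average(secondary_shifts(tab, rc, "HA"), seg), "HA")
      p_ca <- helix_population(
        segment_average(secondary_shifts(tab, rc, "CA"), seg), "CA")
      if (abs(p_ha$percent - 100 * f) <= 3) ok_ha <- ok_ha + 1L
      if (abs(p_ca$percent - 100 * f) <= 7) ok_ca <- ok_ca + 1L
    }
    expect_gte(ok_ha / n_rep, 0.95)
    expect_gte(ok_ca / n_rep, 0.95)
  }
})
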