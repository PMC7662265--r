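# Shared fixtures and independent oracles used across the suite.

cb1_peptide <- function() {
  parse_peptide("CB1", "TVNPIIYALRSKDLRHAFR", 391,
                n_term_mod = "acetyl", c_term_mod = "amide")
}

barr1_peptide <- function() {
  parse_peptide("barr1", "YGREDLDVLGLTFR", 63,
                n_term_mod = "acetyl", c_term_mod = "amide")
}

# Brute-force enumeration of all maximal helical runs: a residue qualifies
# when present in the profile with value < -rc_band; a run is every maximal
# block of consecutive qualifying residue numbers of length >= min_length.
# Independent of the package's single-pass scanner.
oracle_segments <- function(values, rc_band = 0.05, min_length = 3L) {
  nums <- as.integer(names(values))
  qual <- function(k) {
    i <- match(k, nums)
    !is.na(i) && values[i] < -rc_band
  }
  out <- list()
  for (a in nums) for (b in nums) {
    if (b - a + 1L < min_length) next
    if (all(vapply(a:b, qual, logical(1))) && !qual(a - 1L) && !qual(b + 1L))
      out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

segs_to_pairs <- function(segs) {
  lapply(segs, function(s) c(s$first, s$last))
}

# Brute-force minimal superposition RMSD: multi-start random-quaternion
# search refined by Nelder-Mead, entirely independent of the SVD route.
oracle_superpose_rmsd <- function(A, B, n_start = 400L) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  qrot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  f <- function(q) sqrt(mean(rowSums((B0 %*% t(qrot(q)) - A0)^2)))
  starts <- replicate(n_start, stats::rnorm(4), simplify = FALSE)
  vals <- vapply(starts, f, numeric(1))
  best <- Inf
  for (i in order(vals)[1:5]) {
    o <- stats::optim(starts[[i]], f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 10000))
    best <- min(best, o$value)
  }
  best
}

random_rigid_motion <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
              3, 3)
  list(R = R, t = stats::rnorm(3, 0, 10))
}

apply_rigid <- function(model, motion) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  xyz <- xyz %*% t(motion$R) + matrix(motion$t, nrow(xyz), 3, byrow = TRUE)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

# small in-memory shift table from residue/nucleus/ppm triplets
make_shift_table <- function(peptide, numbers, nuclei, ppm,
                             condition = "test") {
  shift_table(peptide,
              data.frame(number = numbers, nucleus = nuclei, ppm = ppm),
              condition = condition)
}
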