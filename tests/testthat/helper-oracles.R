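# Independent oracles used to validate the geometry and metric kernels.
# These deliberately re-derive each quantity from first principles and
# share no code with the implementation paths they check.

# analytic SASA of two intersecting spheres (expanded radii R1, R2 at
# center distance d): each sphere loses the spherical cap cut off by the
# radical plane; accessible area = 4 pi R^2 - 2 pi R h per sphere
two_sphere_sasa_oracle <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  a1 <- 4 * pi * R1^2 - if (h1 > 0) 2 * pi * R1 * h1 else 0
  a2 <- 4 * pi * R2^2 - if (h2 > 0) 2 * pi * R2 * h2 else 0
  a1 + a2
}

# quadratic-time clash count straight from the definition
brute_force_clash_count <- function(xyz, vdw, tol) {
  n <- nrow(xyz)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    cnt <- cnt + sum(d < vdw[i] + vdw[(i + 1):n] - tol)
  }
  cnt
}

# RMSD minimized over rotations parameterized by unit quaternions:
# a grid of starting orientations refined by Nelder-Mead, independent of
# the SVD route
quaternion_rmsd_oracle <- function(moving, fixed) {
  mc <- sweep(moving, 2, colMeans(moving))
  fc <- sweep(fixed, 2, colMeans(fixed))
  rot_of <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  obj <- function(q) {
    if (sum(q^2) < 1e-12) return(1e9)
    sqrt(mean(rowSums((mc %*% rot_of(q) - fc)^2)))
  }
  starts <- rbind(diag(4), -diag(4),
                  matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 1, 0, 0, 1,
                           0, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 1),
                         6, 4, byrow = TRUE))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# lDDT recomputed by explicit enumeration of reference pairs/thresholds
brute_force_lddt <- function(pred_ca, ref_ca, radius = 15,
                             thresholds = c(0.5, 1, 2, 4)) {
  n <- nrow(ref_ca)
  per_thr <- numeric(length(thresholds))
  total <- 0L
  hits <- numeric(length(thresholds))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dr <- sqrt(sum((ref_ca[i, ] - ref_ca[j, ])^2))
    if (dr > radius) next
    total <- total + 1L
    dp <- sqrt(sum((pred_ca[i, ] - pred_ca[j, ])^2))
    hits <- hits + (abs(dp - dr) <= thresholds)
  }
  mean(hits / total)
}

# random single-chain CA structure (each residue its own CA atom)
random_ca_structure <- function(n, spread = 20, chain = "A",
                                name = "random") {
  xyz <- matrix(runif(3 * n, 0, spread), n, 3)
  structure_model(data.frame(
    chain = chain, resseq = seq_len(n), icode = "",
    aa = sample(c("A", "G", "W", "L", "K", "D"), n, replace = TRUE),
    atom = "CA", element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), name = name, validate = FALSE)
}

# random proper rotation matrix
random_rotation_oracle <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# apply a rigid motion to a whole structure
transform_structure <- function(s, rot = diag(3), shift = c(0, 0, 0)) {
  m <- sweep(nanoem::coords(s) %*% rot, 2, shift, `+`)
  s$atoms$x <- m[, 1]; s$atoms$y <- m[, 2]; s$atoms$z <- m[, 3]
  s
}

# minimal PDB text fixture written in code (three residues, one chain)
write_mini_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       3.800   1.500   0.100  1.00  0.00           C",
    "ATOM      5  CA  TRP A   3       7.100   2.100   0.500  1.00  0.00           C",
    "TER       6      TRP A   3",
    "END")
  writeLines(lines, path)
  path
}
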