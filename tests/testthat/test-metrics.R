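test_that("amino-acid recovery counts matching positions", {
  expect_equal(aar("AGW", "AGW"), 1.0)
  expect_equal(aar("AAAA", "AAAT"), 0.75)
  expect_error(aar("AAAAA", "AAAAAA"), "equal lengths")
})

test_that("Kabsch recovers rigid motions exactly", {
  withr::local_seed(11)
  pts <- matrix(rnorm(30, sd = 5), 10, 3)
  rot <- random_rotation_oracle()
  moved <- sweep(pts %*% rot, 2, c(3, -7, 11), `+`)
  sp <- kabsch(moved, pts)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # self-superposition: identity rotation, zero translation
  sp0 <- kabsch(pts, pts)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(sp0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_error(kabsch(pts[1:2, ], pts[1:2, ]), "at least 3")
  # collinear triple still yields a proper rotation
  line <- cbind(c(0, 1, 2), 0, 0)
  spl <- kabsch(line, sweep(line %*% random_rotation_oracle(), 2, 1, `+`))
  expect_equal(det(spl$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the quaternion-minimization oracle", {
  withr::local_seed(23)
  for (rep in 1:5) {
    a <- matrix(rnorm(30, sd = 4), 10, 3)
    b <- sweep(a %*% random_rotation_oracle(), 2, rnorm(3), `+`) +
      matrix(rnorm(30, sd = 0.5), 10, 3)
    expect_equal(kabsch(a, b)$rmsd, quaternion_rmsd_oracle(a, b),
                 tolerance = 1e-4)
  }
})

test_that("region RMSD is framework-anchored and exact on translations", {
  nb <- fixture_nanobody()
  ids <- residue_ids(nb, "H")
  cdrs <- attr(nb, "cdrs")
  h3 <- cdr_residue_ids(nb, "H", cdrs, "H3")
  expect_equal(rmsd_region(nb, nb, ids, ids), 0)
  expect_equal(rmsd_region(nb, nb, h3, ids), 0)
  # displace the H3 loop by exactly 2 A: aligned on the (identical)
  # framework, the loop RMSD is exactly the displacement
  pred <- nb
  rows <- pred$rid %in% h3
  pred$atoms$z[rows] <- pred$atoms$z[rows] - 2
  expect_equal(rmsd_region(pred, nb, h3, align_on = setdiff(ids, h3)),
               2.0, tolerance = 1e-6)
  # anchoring on the whole chain absorbs part of the shift but stays close
  expect_lt(abs(rmsd_region(pred, nb, h3, align_on = ids) - 2.0), 0.2)
  # direct-formula oracle on a random perturbation
  withr::local_seed(5)
  pert <- nb
  disp <- matrix(rnorm(3 * sum(rows), sd = 0.8), ncol = 3)
  pert$atoms[rows, c("x", "y", "z")] <-
    pert$atoms[rows, c("x", "y", "z")] + disp
  want <- sqrt(mean(rowSums(disp^2)))  # alignment on identical framework
  expect_equal(rmsd_region(pert, nb, h3, align_on = setdiff(ids, h3)),
               want, tolerance = 0.05)
  expect_error(rmsd_region(nb, nb, "H999", ids), "does not resolve|missing CA")
})

test_that("TM-score identities and maximization property hold", {
  nb <- fixture_nanobody()
  expect_equal(tm_score(nb, nb), 1.0)
  moved <- transform_structure(nb, random_rotation_oracle(), c(5, 5, 5))
  expect_equal(tm_score(moved, nb), 1.0, tolerance = 1e-9)
  # every residue displaced by exactly d0 in a fixed frame scores 1/2
  L <- length(residue_ids(nb, "H"))
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  shifted <- transform_structure(nb, diag(3), c(0, d0, 0))
  expect_equal(tm_score(shifted, nb, superpose = FALSE), 0.5,
               tolerance = 1e-12)
  # maximization: never below the single whole-chain Kabsch score
  withr::local_seed(17)
  pert <- nb
  pert$atoms[, c("x", "y", "z")] <-
    pert$atoms[, c("x", "y", "z")] + matrix(rnorm(3 * nrow(pert$atoms),
                                                  sd = 1.5), ncol = 3)
  p <- ca_coords(pert); r <- ca_coords(nb)
  sp <- kabsch(p, r)
  d <- sqrt(rowSums((apply_superposition(p, sp) - r)^2))
  single <- mean(1 / (1 + (d / d0)^2))
  expect_gte(tm_score(pert, nb) + 1e-12, single)
  expect_error(tm_score(random_ca_structure(10), random_ca_structure(10)),
               "at least 20")
})

test_that("lDDT matches brute-force enumeration and its identities", {
  nb <- fixture_nanobody()
  expect_equal(lddt(nb, nb), 1.0)
  # blowing the structure up changes every pairwise distance by > 4 A
  blown <- nb
  blown$atoms[, c("x", "y", "z")] <- blown$atoms[, c("x", "y", "z")] * 3
  expect_equal(lddt(blown, nb), 0.0)
  # three-residue toy: one pair distance changed by 3 A
  ref <- structure_model(data.frame(
    chain = "A", resseq = 1:3, icode = "", aa = "A", atom = "CA",
    element = "C", x = c(0, 4, 8), y = 0, z = 0), validate = FALSE)
  pred <- ref
  pred$atoms$x[3] <- 11   # pairs (1,3) and (2,3) stretch by 3 A
  # pairs: (1,2) preserved at all 4 thresholds; (1,3), (2,3) only at 4 A
  want <- mean(c(1, 1, 1, 3) / 3)
  expect_equal(lddt(pred, ref), want)
  expect_equal(brute_force_lddt(ca_coords(pred), ca_coords(ref)), want)
  # random perturbation against the brute-force oracle
  withr::local_seed(71)
  pert <- nb
  pert$atoms[, c("x", "y", "z")] <-
    pert$atoms[, c("x", "y", "z")] + matrix(rnorm(3 * nrow(pert$atoms)),
                                            ncol = 3)
  expect_equal(lddt(pert, nb),
               brute_force_lddt(ca_coords(pert), ca_coords(nb)))
  expect_error(lddt(random_ca_structure(1), random_ca_structure(1)),
               "at least 2")
})

test_that("DockQ is exact on self-comparison and tracks its components", {
  cx <- fixture_complex()
  self <- dockq(cx, cx)
  expect_equal(self$fnat, 1)
  expect_equal(self$lrms, 0, tolerance = 1e-9)
  expect_equal(self$irms, 0, tolerance = 1e-9)
  expect_equal(self$dockq, 1.0, tolerance = 1e-9)
  # translate the ligand away: components computed by brute force
  shift_complex <- function(cx, dz) {
    s <- cx$structure
    rows <- s$atoms$chain == "H"
    s$atoms$z[rows] <- s$atoms$z[rows] + dz
    out <- cx; out$structure <- s
    out
  }
  far <- shift_complex(cx, 40)
  comp <- dockq(far, cx)
  expect_equal(comp$fnat, 0)          # all reference contacts lost
  expect_equal(comp$lrms, 40, tolerance = 1e-6)
  expect_equal(comp$dockq,
               (0 + 1 / (1 + (comp$irms / 1.5)^2) +
                  1 / (1 + (40 / 8.5)^2)) / 3)
  expect_lt(comp$dockq, 1 / 3 + 0.1)
  # monotone decrease along a translation family, all values in [0, 1]
  prev <- Inf
  for (dz in c(0, 1, 2.5, 5, 10, 20)) {
    v <- dockq(shift_complex(cx, dz), cx)$dockq
    expect_gte(v, 0); expect_lte(v, 1)
    expect_lte(v, prev + 1e-9)
    prev <- v
  }
  # empty reference interface is an error
  expect_error(dockq(cx, shift_complex(cx, 100)), "empty interface")
})

test_that("success rate and CI margin match their printed definitions", {
  expect_equal(success_rate(c(-1, 2, -3, 4)), 50.0)
  expect_equal(success_rate(c(1, 2)), 0.0)
  expect_equal(success_rate(c(-1, -2)), 100.0)
  expect_error(success_rate(numeric(0)), "empty")
  expect_equal(ci_margin(rep(3, 10)), 0.0)
  # population sigma = 2 at n = 4 gives exactly 1.96
  x <- c(0, 0, 4, 4)   # mean 2, population sd 2
  expect_equal(ci_margin(x), 1.96)
  expect_error(ci_margin(1), "at least 2")
  # random sample against an independent two-pass computation
  withr::local_seed(13)
  v <- rnorm(50)
  sigma <- sqrt(sum((v - sum(v) / 50)^2) / 50)
  expect_equal(ci_margin(v), 1.96 * sigma / sqrt(50))
  expect_equal(ci_margin(v, sd_type = "sample"),
               1.96 * stats::sd(v) / sqrt(50))
})
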