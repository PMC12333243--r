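test_that("engine suite handshake rejects wrong contracts", {
  expect_s3_class(mock_engine_suite(), "engine_suite")
  expect_error(engine_suite(predictor = mock_docker(),
                            docker = mock_docker(),
                            designer = mock_designer(),
                            packer = mock_packer(),
                            energy = mock_energy(),
                            refiner = mock_minimizer()),
               "structure_predictor")
})

test_that("the predictor threads deterministically with a CDR-local footprint", {
  nb <- fixture_nanobody()
  cdrs <- attr(nb, "cdrs")
  pred <- mock_predictor()
  seq0 <- extract_sequence(nb, "H")
  # unchanged sequence reproduces the template exactly
  same <- pred$predict(seq0, nb, cdrs, "H")
  expect_identical(coords(same), coords(nb))
  # a mutated H3 moves CA atoms only within H3 +/- flanking residues
  aa <- strsplit(seq0, "")[[1]]
  aa[99] <- if (aa[99] == "W") "F" else "W"
  mut <- paste(aa, collapse = "")
  out <- pred$predict(mut, nb, cdrs, "H")
  moved <- which(rowSums(abs(coords(out) - coords(nb))) > 0)
  expect_true(all(moved >= 97 - 2 & moved <= 102 + 2))
  expect_gt(length(moved), 0)
  # bit-identical on repeated calls
  expect_identical(coords(out), coords(pred$predict(mut, nb, cdrs, "H")))
  expect_error(pred$predict("AGW", nb, cdrs, "H"), "length")
})

test_that("the docker is seeded, sorted and epitope-biased", {
  nb <- fixture_nanobody()
  ag <- fixture_antigen()
  epi <- attr(ag, "epitope")
  cdrs <- attr(nb, "cdrs")
  docker <- mock_docker()
  poses <- docker$dock(nb, ag, epi, cdrs, d = 10, seed = 5)
  expect_length(poses, 10)
  scores <- vapply(poses, `[[`, numeric(1), "engine_score")
  expect_true(all(diff(scores) >= 0))   # rank 1 has most contacts
  expect_equal(vapply(poses, `[[`, integer(1), "engine_rank"), 1:10)
  # pure function of (inputs, seed)
  again <- docker$dock(nb, ag, epi, cdrs, d = 10, seed = 5)
  expect_identical(lapply(poses, function(p) coords(p$nanobody)),
                   lapply(again, function(p) coords(p$nanobody)))
  expect_error(docker$dock(nb, ag, epi, cdrs, d = 0, seed = 1), "d must")
  # the transform stored with the pose reproduces the posed coordinates
  p1 <- poses[[1]]
  expect_equal(sweep(coords(nb) %*% p1$rotation, 2, p1$translation, `+`),
               coords(p1$nanobody), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(p1$rotation), 1, tolerance = 1e-9)
  # guidance: the best biased pose puts H3 nearer the epitope than
  # unguided random poses do on average (100-pose sample)
  h3 <- cdr_residue_ids(nb, "H", cdrs, "H3")
  epi_c <- colMeans(ca_coords(ag)[epi$residues, , drop = FALSE])
  h3_dist <- function(p)
    sqrt(sum((colMeans(ca_coords(p$nanobody)[h3, , drop = FALSE]) -
                epi_c)^2))
  unbiased <- mock_docker(bias_fraction = 0)$dock(nb, ag, epi, cdrs,
                                                  d = 100, seed = 6)
  expect_lt(h3_dist(poses[[1]]),
            mean(vapply(unbiased, h3_dist, numeric(1))))
})

test_that("the designer mutates only the selected CDRs, reproducibly", {
  cx <- fixture_complex()
  cdrs <- cx$cdrs
  pred <- mock_predictor()
  designer <- mock_designer()
  nb <- subset_chains(cx$structure, "H")
  seq0 <- strsplit(extract_sequence(nb, "H"), "")[[1]]
  h3_pos <- 97:102
  des <- designer$design(cx, cdrs, "H3", k = 5, seed = 3, predictor = pred)
  expect_length(des, 5)
  for (d in des) {
    diff <- which(strsplit(d$sequence, "")[[1]] != seq0)
    expect_gte(length(diff), 1)
    expect_lte(length(diff), 3)
    expect_true(all(diff %in% h3_pos))
  }
  # selecting all three CDRs widens the allowed footprint
  all_pos <- c(26:33, 50:57, h3_pos)
  des_all <- designer$design(cx, cdrs, c("H1", "H2", "H3"), k = 8,
                             seed = 4, predictor = pred)
  expect_true(all(unlist(lapply(des_all, function(d)
    which(strsplit(d$sequence, "")[[1]] != seq0))) %in% all_pos))
  # fixed seed reproduces the same k sequences
  des2 <- designer$design(cx, cdrs, "H3", k = 5, seed = 3,
                          predictor = pred)
  expect_identical(vapply(des, `[[`, character(1), "sequence"),
                   vapply(des2, `[[`, character(1), "sequence"))
  expect_error(designer$design(cx, cdrs, character(0), k = 2, seed = 1,
                               predictor = pred), "empty CDR")
})

test_that("the packer preserves the backbone, skips glycine, idempotent", {
  cx <- fixture_complex()
  packer <- mock_packer()
  packed <- packer$pack(cx)
  s0 <- cx$structure; s1 <- packed$structure
  expect_equal(ca_coords(s1, "H"), ca_coords(s0, "H"))
  expect_identical(coords(subset_chains(s1, "A")),
                   coords(subset_chains(s0, "A")))
  a1 <- s1$atoms
  gly <- unique(s1$rid[a1$chain == "H" & a1$aa == "G"])
  cb_res <- unique(s1$rid[a1$chain == "H" & a1$atom == "CB"])
  expect_length(intersect(gly, cb_res), 0)
  nongly <- setdiff(unique(s1$rid[a1$chain == "H"]), gly)
  expect_setequal(cb_res, nongly)
  # CB sits 1.53 A from its CA
  for (rid in cb_res[1:5]) {
    rows <- a1[s1$rid == rid, ]
    d <- sqrt(sum((as.numeric(rows[rows$atom == "CB", c("x", "y", "z")]) -
                     as.numeric(rows[rows$atom == "CA",
                                     c("x", "y", "z")]))^2))
    expect_equal(d, 1.53, tolerance = 1e-9)
  }
  # pack(pack(x)) == pack(x)
  twice <- packer$pack(packed)
  expect_identical(twice$structure$atoms, packed$structure$atoms)
})

test_that("the energy model scores contacts by the planted table", {
  eng <- mock_energy()
  cx <- fixture_complex()
  # identical complex as its own reference: ddG = 0, delta = ddG
  rep_self <- eng$evaluate(cx, reference = cx)
  expect_equal(rep_self$ddG, 0)
  expect_equal(rep_self$delta, 0)
  # separated chains score exactly zero
  far <- cx
  s <- far$structure
  rows <- s$atoms$chain == "H"
  s$atoms$y[rows] <- s$atoms$y[rows] - 500
  far$structure <- s
  expect_equal(eng$evaluate(far)$dG, 0)
  # without a reference, delta is the absolute energy
  rep_dn <- eng$evaluate(cx)
  expect_equal(rep_dn$delta, rep_dn$dG)
  expect_true(is.na(rep_dn$ddG))
  # the affinity table has a strict unique optimum per antigen residue
  tab <- mock_energy_table()
  for (b in colnames(tab)) {
    best <- rownames(tab)[which.min(tab[, b])]
    expect_equal(best, planted_complement(b))
    expect_equal(sum(tab[, b] == min(tab[, b])), 1)
  }
})

test_that("the planted-optimal CDRH3 is a strict local optimum", {
  cx <- fixture_complex()
  eng <- mock_energy()
  pred <- mock_predictor()
  tab <- mock_energy_table()
  s <- cx$structure
  nb <- subset_chains(s, "H"); ag <- subset_chains(s, "A")
  h3_ids <- cdr_residue_ids(s, "H", cx$cdrs, "H3")
  # closed-form per-position optimum from the fixture's CA contact sets
  nbca <- ca_coords(s, "H"); agca <- ca_coords(s, "A")
  aa_of <- stats::setNames(s$atoms$aa[!duplicated(s$rid)],
                           s$rid[!duplicated(s$rid)])
  opt <- vapply(h3_ids, function(rid) {
    d <- sqrt(colSums((t(agca) - nbca[rid, ])^2))
    contacts <- rownames(agca)[d < 8]
    names(which.min(rowSums(tab[, aa_of[contacts], drop = FALSE])))
  }, character(1))
  all_ids <- residue_ids(nb, "H")
  h3_pos <- match(h3_ids, all_ids)
  base <- strsplit(extract_sequence(nb, "H"), "")[[1]]
  thread_dg <- function(seqvec) {
    st <- pred$predict(paste(seqvec, collapse = ""), nb, cx$cdrs, "H")
    eng$evaluate(assemble_complex(st, ag))$dG
  }
  optvec <- base
  optvec[h3_pos] <- opt
  dg_opt <- thread_dg(optvec)
  # brute force over all 19 x L single substitutions, via the full
  # threading + energy path
  for (p in h3_pos) {
    for (a in setdiff(rownames(tab), optvec[p])) {
      mv <- optvec
      mv[p] <- a
      expect_gt(thread_dg(mv), dg_opt)
    }
  }
})

test_that("fixture construction honours its guarantees", {
  expect_equal(n_clashes(detect_clashes(fixture_complex()$structure)), 0)
  cx3 <- make_fixture("complex", clashes = 3)
  rep3 <- detect_clashes(cx3$structure)
  expect_equal(rep3$inter_clashes, 3)
  # planted pairs confirmed by the brute-force oracle
  s <- cx3$structure
  expect_identical(
    n_clashes(rep3),
    as.integer(brute_force_clash_count(coords(s), s$atoms$vdw, 0.4)))
  expect_error(fixture_antigen(dims = c(2, 2, 1)), "at least 12")
  # the nanobody fixture's heuristic H3 equals the planted range
  nb <- make_fixture("nanobody")
  expect_equal(locate_cdrs(nb, "H")$cdr_ranges$H3,
               attr(nb, "cdrs")$cdr_ranges$H3)
})
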