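fx <- local({
  nb <- fixture_nanobody()
  list(nb = nb, ag = fixture_antigen(), cdrs = attr(nb, "cdrs"),
       epi = attr(fixture_antigen(), "epitope"),
       engines = mock_engine_suite())
})

test_that("run configuration validates its dimensions", {
  expect_error(run_config(r = 0), ">= 1")
  expect_error(run_config(r = 2, d = 2, n = 5), "n must not exceed")
  expect_error(run_config(cdrs_to_design = "H9"), "subset")
  cfg <- run_config(r = 2, d = 4, n = 2, k = 3, iterations = 2, seed = 9)
  expect_s3_class(cfg, "run_config")
})

test_that("lineage initialization randomizes only the CDRH3", {
  cands <- initialize_lineages(fx$nb, fx$cdrs, r = 3, seed = 5,
                               engines = fx$engines)
  expect_length(cands, 3)
  expect_equal(vapply(cands, `[[`, integer(1), "lineage_id"), 1:3)
  seq0 <- strsplit(extract_sequence(fx$nb, "H"), "")[[1]]
  for (cand in cands) {
    diff <- which(strsplit(cand$sequence, "")[[1]] != seq0)
    expect_true(all(diff %in% 97:102))
  }
  again <- initialize_lineages(fx$nb, fx$cdrs, r = 3, seed = 5,
                               engines = fx$engines)
  expect_identical(vapply(cands, `[[`, character(1), "sequence"),
                   vapply(again, `[[`, character(1), "sequence"))
  expect_error(initialize_lineages(fx$nb, fx$cdrs, r = 0, seed = 1,
                                   engines = fx$engines), ">= 1")
})

test_that("the E-step ranks survivors by epitope recall and selects top-n", {
  cfg <- run_config(r = 1, d = 6, n = 2, k = 2, iterations = 1, seed = 21)
  cands <- initialize_lineages(fx$nb, fx$cdrs, r = 1, seed = 21,
                               engines = fx$engines)
  es <- e_step(cands, fx$ag, fx$epi, fx$cdrs, cfg, fx$engines,
               iteration = 1)
  expect_lte(length(es$complexes), 2)
  expect_equal(es$pool_after_docking, 6)
  expect_gte(es$pool_after_qc, length(es$complexes))
  recalls <- vapply(es$complexes, `[[`, numeric(1), "recall")
  expect_true(all(diff(recalls) <= 0))   # non-increasing
  expect_true(all(recalls >= 0 & recalls <= 1))
})

test_that("iteration-1 M-step pool equals r x n x k before QC", {
  cfg <- run_config(r = 2, d = 6, n = 2, k = 3, iterations = 1, seed = 33)
  cands <- initialize_lineages(fx$nb, fx$cdrs, r = 2, seed = 33,
                               engines = fx$engines)
  es <- e_step(cands, fx$ag, fx$epi, fx$cdrs, cfg, fx$engines, 1)
  expect_length(es$complexes, 2 * 2)   # n per lineage in iteration 1
  ms <- m_step(es$complexes, fx$cdrs, cfg, fx$engines, fx$epi, 1)
  expect_equal(ms$pool_before_qc, 2 * 2 * 3)
  deltas <- vapply(ms$candidates, function(x) x$energy$delta, numeric(1))
  expect_true(all(diff(deltas) >= 0))  # sorted ascending
  expect_true(all(vapply(ms$candidates, function(x) x$qc$passed,
                         logical(1))))
})

test_that("optimization mode demands and uses a reference complex", {
  cfg <- run_config(mode = "optimize", r = 1, d = 4, n = 1, k = 2,
                    iterations = 1, seed = 3)
  cands <- initialize_lineages(fx$nb, fx$cdrs, r = 1, seed = 3,
                               engines = fx$engines)
  es <- e_step(cands, fx$ag, fx$epi, fx$cdrs, cfg, fx$engines, 1)
  expect_error(m_step(es$complexes, fx$cdrs, cfg, fx$engines, fx$epi, 1),
               "reference")
  ref <- fixture_complex()
  ms <- m_step(es$complexes, fx$cdrs, cfg, fx$engines, fx$epi, 1,
               reference = ref)
  for (cand in ms$candidates)
    expect_equal(cand$energy$delta, cand$energy$ddG)
})

test_that("beam selection keeps lineages in iteration 1, top-n later", {
  mk <- function(lineage, delta, id)
    list(id = id, lineage_id = lineage,
         energy = list(delta = delta, dG = delta, ddG = NA))
  pool <- list(mk(1, -9, "a"), mk(2, -8, "b"), mk(1, -7, "c"),
               mk(3, -6, "d"), mk(2, -5, "e"), mk(3, -4, "f"),
               mk(1, -3, "g"), mk(2, -2, "h"))
  sel1 <- select_beam(pool, n = 2, iteration = 1, r = 3)
  expect_equal(vapply(sel1, `[[`, character(1), "id"), c("a", "b", "d"))
  sel2 <- select_beam(pool, n = 2, iteration = 2, r = 3)
  expect_equal(vapply(sel2, `[[`, character(1), "id"), c("a", "b"))
  one <- select_beam(list(mk(1, -2, "x"), mk(1, -1, "y")), n = 3,
                     iteration = 1, r = 3)
  expect_length(one, 1)
  expect_error(select_beam(list(), 2, 1, 3), class = "nanoem_exhaustion")
})

test_that("a full run traces its pools and improves monotonically", {
  cfg <- run_config(r = 2, d = 6, n = 2, k = 3, iterations = 3, seed = 8)
  run <- run_nanoem(cfg, fx$nb, fx$ag, fx$epi, fx$cdrs,
                    engines = fx$engines)
  expect_s3_class(run, "nanoem_run")
  expect_length(run$trace, 3)
  best <- vapply(run$trace, `[[`, numeric(1), "best_delta_so_far")
  expect_true(all(diff(best) <= 0))
  expect_equal(run$best_delta, best[3])
  expect_equal(run$trace[[1]]$pool_size_after_design, 2 * 2 * 3)
  expect_named(run$ledger,
               c("id", "lineage", "iteration", "delta", "dG", "ddG",
                 "recall", "clashes", "sequence"))
  expect_true(all(run$ledger$clashes == 0))
  # outputs are written on request
  out_dir <- withr::local_tempdir()
  write_run_outputs(run, out_dir)
  expect_true(file.exists(file.path(out_dir, "ledger.tsv")))
  expect_true(file.exists(file.path(out_dir, "trace.json")))
  expect_gt(length(list.files(out_dir, pattern = "[.]pdb$")), 0)
})

test_that("optional early stopping truncates a stalled run", {
  cfg <- run_config(r = 2, d = 6, n = 2, k = 3, iterations = 6, seed = 8,
                    early_stop = TRUE, early_stop_tol = 1e9)
  run <- run_nanoem(cfg, fx$nb, fx$ag, fx$epi, fx$cdrs,
                    engines = fx$engines)
  # any improvement is below the (absurd) tolerance, so the run stops at
  # the earliest permitted point
  expect_length(run$trace, 3)
  expect_length(run$timings, 3)
  # off by default: same configuration runs to completion
  cfg_off <- run_config(r = 2, d = 6, n = 2, k = 3, iterations = 4,
                        seed = 8)
  expect_length(run_nanoem(cfg_off, fx$nb, fx$ag, fx$epi, fx$cdrs,
                           engines = fx$engines)$trace, 4)
})

test_that("when every pose is filtered the pipeline exhausts loudly", {
  # an unsatisfiably strict burial threshold: no residue can ever belong
  # to the interface, so both interface filters reject every pose
  cfg <- run_config(r = 1, d = 3, n = 1, k = 2, iterations = 1, seed = 2,
                    dsasa_threshold = 1e6)
  err <- expect_error(
    run_nanoem(cfg, fx$nb, fx$ag, fx$epi, fx$cdrs, engines = fx$engines),
    class = "nanoem_exhaustion")
  expect_match(conditionMessage(err), "dominant reason")
  expect_true(err$dominant_reason %in%
                c("cdrh3_not_in_interface", "epitope_not_in_interface"))
  expect_equal(err$iteration, 1)
})

test_that("evaluating reference self-copies gives perfect scores", {
  ref <- fixture_complex()
  nb <- subset_chains(ref$structure, "H")
  cand <- list(id = "self", sequence = extract_sequence(nb, "H"),
               structure = nb, complex = ref,
               energy = list(dG = -50, ddG = 0, delta = 0))
  ev <- evaluate_run(list(cand, cand), reference_truth = ref,
                     cdrs = ref$cdrs)
  expect_equal(ev$scores$aar_h3, c(1, 1))
  expect_equal(ev$scores$rmsd_global, c(0, 0), tolerance = 1e-9)
  expect_equal(ev$scores$rmsd_cdrh3, c(0, 0), tolerance = 1e-9)
  expect_equal(ev$scores$dockq, c(1, 1), tolerance = 1e-9)
  expect_equal(ev$scores$ddG, c(0, 0))
  expect_equal(ev$success_rate, 0)      # ddG of 0 is not an improvement
  expect_equal(unname(ev$summary["dockq", "margin"]), 0)
  # the printed success-rate definition on a mixed pool
  mixed <- lapply(c(-1, -2, 3), function(dd) {
    x <- cand; x$energy$ddG <- dd; x
  })
  ev2 <- evaluate_run(mixed, cdrs = ref$cdrs)
  expect_equal(ev2$success_rate, 200 / 3, tolerance = 1e-9)
})
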