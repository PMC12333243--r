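#' @name em-pipeline
#' @title The design/optimization expectation-maximization loop
#'
#' @description
#' The pipeline alternates between an E-step that generates candidate
#' complexes for the current CDRH3 guesses (docking, refinement, clash and
#' interface quality control, epitope-recall ranking, beam selection) and
#' an M-step that designs new CDRH3 loops for the selected complexes
#' (generative proposal, side-chain packing, quality control,
#' binding-energy ranking). A beam of the `n` best designs seeds the next
#' iteration; in the first iteration the best design of each of the `r`
#' initial lineages is kept instead, preserving diversity while binding
#' affinities are still equilibrating.
NULL

#' Pipeline run configuration
#'
#' @param mode `"denovo"` ranks designs by predicted absolute binding
#'   free energy dG; `"optimize"` ranks by ddG relative to a reference
#'   complex (which must then be supplied to [run_nanoem()]).
#' @param r number of random-CDRH3 lineages at initialization.
#' @param d docked poses generated per nanobody.
#' @param n beam width.
#' @param k designs per complex.
#' @param iterations number of EM iterations T.
#' @param cdrs_to_design subset of `c("H1","H2","H3")` to redesign.
#' @param seed master seed; all stage randomness is derived from it via
#'   [substream_seed()].
#' @param dsasa_threshold interface burial threshold (A^2).
#' @param contact_cutoff per-CDR contact cutoff (A).
#' @param overlap_tolerance clash tolerance (A).
#' @param sasa_n_points sphere-sampling count for pipeline-internal
#'   interface detection.
#' @param probe_radius SASA probe radius (A).
#' @param refine_max_steps refinement iteration budget per pose.
#' @param early_stop stop before `iterations` when the best delta has
#'   improved by less than `early_stop_tol` over two consecutive
#'   iterations. Off by default, matching a fixed-iteration protocol.
#' @param early_stop_tol improvement threshold (kcal/mol).
#' @return a `run_config`.
#' @export
run_config <- function(mode = c("denovo", "optimize"), r = 4, d = 20,
                       n = 4, k = 8, iterations = 10,
                       cdrs_to_design = "H3", seed = 1,
                       dsasa_threshold = 1.0, contact_cutoff = 5.0,
                       overlap_tolerance = 0.4, sasa_n_points = 320,
                       probe_radius = 1.4, refine_max_steps = 200,
                       early_stop = FALSE, early_stop_tol = 0.01) {
  mode <- match.arg(mode)
  if (any(c(r, d, n, k, iterations) < 1))
    stop("r, d, n, k and iterations must all be >= 1")
  if (n > r * d)
    stop("beam width n must not exceed r * d (first E-step feasibility)")
  if (!all(cdrs_to_design %in% c("H1", "H2", "H3")) ||
      length(cdrs_to_design) == 0)
    stop("cdrs_to_design must be a non-empty subset of H1/H2/H3")
  out <- list(mode = mode, r = as.integer(r), d = as.integer(d),
              n = as.integer(n), k = as.integer(k),
              iterations = as.integer(iterations),
              cdrs_to_design = cdrs_to_design, seed = as.integer(seed),
              dsasa_threshold = dsasa_threshold,
              contact_cutoff = contact_cutoff,
              overlap_tolerance = overlap_tolerance,
              sasa_n_points = as.integer(sasa_n_points),
              probe_radius = probe_radius,
              refine_max_steps = as.integer(refine_max_steps),
              early_stop = isTRUE(early_stop),
              early_stop_tol = early_stop_tol)
  class(out) <- "run_config"
  out
}

exhaustion <- function(msg, iteration = NA, reason = NA) {
  stop(errorCondition(msg, iteration = iteration, dominant_reason = reason,
                      class = c("nanoem_exhaustion", "error", "condition")))
}

#' Initialize design lineages with randomized CDRH3 loops
#'
#' The scaffold's CDRH3 positions are replaced by uniform-random residues
#' (length preserved, framework untouched) `r` times; each randomized
#' sequence is folded by the structure predictor.
#'
#' @param scaffold nanobody `nano_structure` (single chain).
#' @param cdrs `cdr_annotation` on the scaffold.
#' @param r lineage count.
#' @param seed master seed.
#' @param engines an `engine_suite`.
#' @return list of candidate records with lineage ids `1..r`.
#' @export
initialize_lineages <- function(scaffold, cdrs, r, seed, engines) {
  if (r < 1) stop("r must be >= 1")
  chain_id <- chain_ids(scaffold)[1]
  aa <- strsplit(extract_sequence(scaffold, chain_id), "")[[1]]
  h3 <- cdr_positions(scaffold, chain_id, cdrs, "H3")
  lapply(seq_len(r), function(l) {
    new <- aa
    new[h3] <- with_seed(substream_seed(seed, "init", 0L, l),
                         sample(AA_ONE, length(h3), replace = TRUE))
    seqc <- paste(new, collapse = "")
    list(id = sprintf("it0-L%d", l), lineage_id = l, iteration = 0L,
         sequence = seqc,
         structure = engines$predictor$predict(seqc, scaffold, cdrs,
                                               chain_id),
         parent_id = NA_character_)
  })
}

# dock one candidate, QC every pose, return survivors with recall
qc_poses_for_candidate <- function(cand, antigen, epitope, cdrs, config,
                                   engines, iteration, index) {
  poses <- engines$docker$dock(
    cand$structure, antigen, epitope, cdrs, config$d,
    seed = substream_seed(config$seed, "dock", iteration, index))
  out <- vector("list", length(poses))
  reasons <- character(0)
  for (p in seq_along(poses)) {
    cx <- assemble_complex(poses[[p]]$nanobody, antigen,
                           lineage = cand$lineage_id,
                           iteration = iteration,
                           engine_rank = poses[[p]]$engine_rank,
                           engine_score = poses[[p]]$engine_score)
    cx$structure <- refine(cx$structure, engines$refiner,
                           config$refine_max_steps)
    clash <- detect_clashes(cx$structure, config$overlap_tolerance)
    iface <- compute_interface(cx, cdrs, config$dsasa_threshold,
                               config$contact_cutoff, config$probe_radius,
                               config$sasa_n_points)
    outcome <- apply_complex_filters(cx, cdrs, epitope, iface, clash)
    if (outcome$passed) {
      cx$recall <- epitope_recall(epitope, iface)
      cx$recall_overlap <- length(intersect(epitope$residues,
                                            iface$epitope_residues))
      cx$iface <- iface
      cx$parent_id <- cand$id
      out[[p]] <- cx
    } else {
      reasons <- c(reasons, outcome$reasons)
    }
  }
  list(survivors = Filter(Negate(is.null), out), reasons = reasons)
}

#' E-step: generate, filter and select candidate complexes
#'
#' Each candidate nanobody is docked into `d` poses; every pose is
#' refined, clash-checked and interface-checked; survivors are ranked by
#' epitope recall (ties: larger desired-epitope overlap, then docking
#' rank). In iteration 1 the top `n` poses are kept per lineage; in later
#' iterations the top `n` overall.
#'
#' @param candidates list of candidate records (see
#'   [initialize_lineages()]).
#' @param antigen antigen `nano_structure`.
#' @param epitope desired `epitope_spec`.
#' @param cdrs `cdr_annotation`.
#' @param config a `run_config`.
#' @param engines an `engine_suite`.
#' @param iteration 1-based iteration index.
#' @return list with `complexes` (selected `complex_model`s),
#'   `pool_after_docking`, `pool_after_qc`.
#' @export
e_step <- function(candidates, antigen, epitope, cdrs, config, engines,
                   iteration) {
  if (length(candidates) == 0) stop("no candidates to dock")
  all_surv <- list()
  all_reasons <- character(0)
  n_poses <- 0L
  for (i in seq_along(candidates)) {
    qc <- qc_poses_for_candidate(candidates[[i]], antigen, epitope, cdrs,
                                 config, engines, iteration, i)
    n_poses <- n_poses + config$d
    all_surv <- c(all_surv, qc$survivors)
    all_reasons <- c(all_reasons, qc$reasons)
  }
  if (length(all_surv) == 0) {
    tab <- sort(table(all_reasons), decreasing = TRUE)
    exhaustion(sprintf(
      "E-step exhausted at iteration %d: all %d poses filtered (dominant reason: %s)",
      iteration, n_poses, names(tab)[1]),
      iteration = iteration, reason = names(tab)[1])
  }
  rank_order <- function(cxs) {
    order(-vapply(cxs, `[[`, numeric(1), "recall"),
          -vapply(cxs, `[[`, numeric(1), "recall_overlap"),
          vapply(cxs, `[[`, numeric(1), "engine_rank"))
  }
  if (iteration == 1) {
    lineages <- vapply(all_surv, `[[`, numeric(1), "lineage")
    selected <- unlist(lapply(sort(unique(lineages)), function(l) {
      mine <- all_surv[lineages == l]
      mine[utils::head(rank_order(mine), config$n)]
    }), recursive = FALSE)
  } else {
    selected <- all_surv[utils::head(rank_order(all_surv), config$n)]
  }
  list(complexes = selected, pool_after_docking = n_poses,
       pool_after_qc = length(all_surv))
}

#' M-step: design, pack, filter and rank CDRH3 candidates
#'
#' For each selected complex the designer proposes `k` candidates over
#' the configured CDRs; each is side-chain packed, refined (clashes
#' introduced by threading or packing are resolved where possible),
#' re-screened (clashes and interface involvement, including the epitope
#' filter on the inherited pose) and energy-ranked with delta = dG (de
#' novo) or ddG (optimization). Survivors are returned sorted by delta ascending.
#'
#' @param complexes list of `complex_model`s from [e_step()].
#' @param cdrs `cdr_annotation`.
#' @param config a `run_config`.
#' @param engines an `engine_suite`.
#' @param epitope desired `epitope_spec`.
#' @param iteration 1-based iteration index.
#' @param reference reference `complex_model`, required in optimization
#'   mode.
#' @return list with `candidates` (sorted), `pool_before_qc`
#'   (`k * length(complexes)`), `pool_after_qc`.
#' @export
m_step <- function(complexes, cdrs, config, engines, epitope, iteration,
                   reference = NULL) {
  if (length(complexes) == 0) stop("no complexes to design against")
  if (config$mode == "optimize" && is.null(reference))
    stop("optimization mode requires a reference complex")
  ref <- if (config$mode == "optimize") reference else NULL
  cands <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    ag <- subset_chains(cx$structure, cx$ag_chains)
    designs <- engines$designer$design(
      cx, cdrs, config$cdrs_to_design, config$k,
      seed = substream_seed(config$seed, "design", iteration, ci),
      predictor = engines$predictor)
    for (ki in seq_along(designs)) {
      des <- designs[[ki]]
      dcx <- assemble_complex(des$structure, ag, lineage = cx$lineage,
                              iteration = iteration,
                              engine_rank = cx$engine_rank,
                              engine_score = cx$engine_score)
      dcx <- engines$packer$pack(dcx)
      dcx$structure <- refine(dcx$structure, engines$refiner,
                              config$refine_max_steps)
      clash <- detect_clashes(dcx$structure, config$overlap_tolerance)
      iface <- compute_interface(dcx, cdrs, config$dsasa_threshold,
                                 config$contact_cutoff,
                                 config$probe_radius,
                                 config$sasa_n_points)
      outcome <- apply_complex_filters(dcx, cdrs, epitope, iface, clash)
      if (!outcome$passed) next
      energy <- engines$energy$evaluate(dcx, ref)
      cands[[length(cands) + 1]] <- list(
        id = sprintf("it%d-c%02d-k%02d", iteration, ci, ki),
        lineage_id = cx$lineage, iteration = iteration,
        sequence = des$sequence,
        structure = subset_chains(dcx$structure, dcx$nb_chain),
        complex = dcx, energy = energy, qc = outcome,
        recall = cx$recall, parent_id = cx$parent_id)
    }
  }
  if (length(cands) == 0)
    exhaustion(sprintf(
      "M-step exhausted at iteration %d: all %d designs failed QC",
      iteration, config$k * length(complexes)),
      iteration = iteration, reason = "design_qc")
  delta <- vapply(cands, function(x) x$energy$delta, numeric(1))
  lineage <- vapply(cands, `[[`, numeric(1), "lineage_id")
  cands <- cands[order(delta, lineage, seq_along(cands))]
  list(candidates = cands,
       pool_before_qc = config$k * length(complexes),
       pool_after_qc = length(cands))
}

#' Beam selection with first-iteration lineage elitism
#'
#' Iteration 1 keeps the best (lowest-delta) candidate of each lineage,
#' up to `r` survivors; later iterations keep the global top `n` by
#' delta regardless of lineage. Input must be delta-sorted (as returned
#' by [m_step()]); ties resolve by lineage id then insertion order.
#'
#' @param candidates delta-sorted candidate list.
#' @param n beam width.
#' @param iteration 1-based iteration index.
#' @param r lineage count.
#' @return the selected candidates, delta-sorted.
#' @export
select_beam <- function(candidates, n, iteration, r) {
  if (length(candidates) == 0)
    exhaustion("beam selection received no candidates",
               iteration = iteration, reason = "empty_pool")
  if (iteration == 1) {
    lineage <- vapply(candidates, `[[`, numeric(1), "lineage_id")
    candidates[!duplicated(lineage)]
  } else {
    utils::head(candidates, n)
  }
}

#' Run the full design/optimization loop
#'
#' Executes initialization, then `iterations` rounds of E-step, M-step
#' and beam selection, recording a per-iteration trace and a ledger of
#' every QC-passed design. Fully reproducible from `(config, seed)`.
#'
#' @param config a `run_config`.
#' @param scaffold nanobody scaffold `nano_structure`.
#' @param antigen antigen `nano_structure`.
#' @param epitope desired `epitope_spec`.
#' @param cdrs optional `cdr_annotation`; located heuristically when
#'   absent.
#' @param reference reference `complex_model` (required in optimization
#'   mode; must be clash-free).
#' @param engines an `engine_suite`.
#' @param out_dir optional output directory for PDB files, `ledger.tsv`
#'   and `trace.json`.
#' @return a `nanoem_run`: list with `final` (the last beam), `trace`
#'   (per-iteration records), `ledger` (data.frame), `best_delta`
#'   (running minimum delta), `timings` (seconds per iteration),
#'   `config`.
#' @export
run_nanoem <- function(config, scaffold, antigen, epitope, cdrs = NULL,
                       reference = NULL, engines = mock_engine_suite(),
                       out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  nb_chain <- chain_ids(scaffold)[1]
  if (is.null(cdrs)) cdrs <- locate_cdrs(scaffold, nb_chain)
  validate_epitope(epitope, antigen, chain_ids(antigen))
  if (config$mode == "optimize") {
    if (is.null(reference))
      stop("optimization mode requires a reference complex")
    if (n_clashes(detect_clashes(reference$structure,
                                 config$overlap_tolerance)) > 0)
      stop("reference complex fails QC (contains clashes)")
  }
  cands <- initialize_lineages(scaffold, cdrs, config$r, config$seed,
                               engines)
  trace <- vector("list", config$iterations)
  ledger <- list()
  best <- Inf
  best_history <- numeric(0)
  timings <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    t_start <- Sys.time()
    es <- tryCatch(
      e_step(cands, antigen, epitope, cdrs, config, engines, t),
      nanoem_exhaustion = function(e) stop(e))
    ms <- m_step(es$complexes, cdrs, config, engines, epitope, t,
                 reference = reference)
    best <- min(best, ms$candidates[[1]]$energy$delta)
    beam <- select_beam(ms$candidates, config$n, t, config$r)
    ledger[[t]] <- do.call(rbind, lapply(ms$candidates, function(x)
      data.frame(id = x$id, lineage = x$lineage_id, iteration = t,
                 delta = x$energy$delta, dG = x$energy$dG,
                 ddG = x$energy$ddG, recall = x$recall, clashes = 0L,
                 sequence = x$sequence, stringsAsFactors = FALSE)))
    trace[[t]] <- list(
      iteration = t, pool_size_after_docking = es$pool_after_docking,
      pool_size_after_qc = es$pool_after_qc,
      pool_size_after_design = ms$pool_before_qc,
      pool_size_after_design_qc = ms$pool_after_qc,
      selected_ids = vapply(beam, `[[`, character(1), "id"),
      best_delta_so_far = best)
    timings[t] <- as.numeric(Sys.time() - t_start, units = "secs")
    cands <- beam
    best_history <- c(best_history, best)
    if (config$early_stop && t >= 3 &&
        best_history[t - 2] - best < config$early_stop_tol) {
      trace <- trace[seq_len(t)]
      timings <- timings[seq_len(t)]
      break
    }
  }
  out <- list(final = cands, trace = trace,
              ledger = do.call(rbind, ledger), best_delta = best,
              timings = timings, config = config)
  class(out) <- "nanoem_run"
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.nanoem_run <- function(x, ...) {
  cat("<nanoem_run> ", x$config$mode, ", ", length(x$trace),
      " iteration(s), final beam ", length(x$final),
      ", best delta ", format(x$best_delta, digits = 4), " kcal/mol\n",
      sep = "")
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Per-candidate complex PDB files, the design ledger as TSV, and the
#' iteration trace as JSON.
#'
#' @param run a `nanoem_run`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cand in run$final)
    write_pdb(cand$complex$structure,
              file.path(out_dir, paste0(cand$id, ".pdb")))
  utils::write.table(run$ledger, file.path(out_dir, "ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$trace, file.path(out_dir, "trace.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Linear (non-iterative) baseline workflow
#'
#' The comparator pipeline: randomize, dock, filter, rank by epitope
#' recall (top `n` per lineage), design once, pack, filter, rank by
#' delta, and keep the best design per lineage. Coded straight-line and
#' independently of the EM loop; with matching seeds it reproduces a
#' single-iteration [run_nanoem()] candidate-for-candidate.
#'
#' @inheritParams run_nanoem
#' @return a `nanoem_run` with one trace entry.
#' @export
run_linear <- function(config, scaffold, antigen, epitope, cdrs = NULL,
                       reference = NULL, engines = mock_engine_suite(),
                       out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  nb_chain <- chain_ids(scaffold)[1]
  if (is.null(cdrs)) cdrs <- locate_cdrs(scaffold, nb_chain)
  validate_epitope(epitope, antigen, chain_ids(antigen))
  ref <- if (config$mode == "optimize") reference else NULL
  if (config$mode == "optimize" && is.null(reference))
    stop("optimization mode requires a reference complex")
  # 1. randomize the CDRH3 r times and predict each structure
  cands <- initialize_lineages(scaffold, cdrs, config$r, config$seed,
                               engines)
  # 2. dock, QC, rank by epitope recall; keep top n per lineage
  selected <- list()
  n_surv <- 0L
  for (i in seq_along(cands)) {
    qc <- qc_poses_for_candidate(cands[[i]], antigen, epitope, cdrs,
                                 config, engines, 1L, i)
    surv <- qc$survivors
    n_surv <- n_surv + length(surv)
    if (length(surv) == 0) next
    ord <- order(-vapply(surv, `[[`, numeric(1), "recall"),
                 -vapply(surv, `[[`, numeric(1), "recall_overlap"),
                 vapply(surv, `[[`, numeric(1), "engine_rank"))
    selected <- c(selected, surv[utils::head(ord, config$n)])
  }
  if (length(selected) == 0)
    exhaustion("linear workflow: no pose survived quality control",
               iteration = 1L, reason = "pose_qc")
  # 3. one round of design + packing + QC + energy ranking
  finals <- list()
  for (ci in seq_along(selected)) {
    cx <- selected[[ci]]
    ag <- subset_chains(cx$structure, cx$ag_chains)
    designs <- engines$designer$design(
      cx, cdrs, config$cdrs_to_design, config$k,
      seed = substream_seed(config$seed, "design", 1L, ci),
      predictor = engines$predictor)
    for (ki in seq_along(designs)) {
      des <- designs[[ki]]
      dcx <- assemble_complex(des$structure, ag, lineage = cx$lineage,
                              iteration = 1L)
      dcx <- engines$packer$pack(dcx)
      dcx$structure <- refine(dcx$structure, engines$refiner,
                              config$refine_max_steps)
      clash <- detect_clashes(dcx$structure, config$overlap_tolerance)
      iface <- compute_interface(dcx, cdrs, config$dsasa_threshold,
                                 config$contact_cutoff,
                                 config$probe_radius,
                                 config$sasa_n_points)
      if (!apply_complex_filters(dcx, cdrs, epitope, iface,
                                 clash)$passed) next
      energy <- engines$energy$evaluate(dcx, ref)
      finals[[length(finals) + 1]] <- list(
        id = sprintf("it1-c%02d-k%02d", ci, ki),
        lineage_id = cx$lineage, iteration = 1L,
        sequence = des$sequence,
        structure = subset_chains(dcx$structure, dcx$nb_chain),
        complex = dcx, energy = energy, recall = cx$recall,
        parent_id = cx$parent_id)
    }
  }
  if (length(finals) == 0)
    exhaustion("linear workflow: all designs failed QC",
               iteration = 1L, reason = "design_qc")
  delta <- vapply(finals, function(x) x$energy$delta, numeric(1))
  lineage <- vapply(finals, `[[`, numeric(1), "lineage_id")
  finals <- finals[order(delta, lineage, seq_along(finals))]
  ledger <- do.call(rbind, lapply(finals, function(x)
    data.frame(id = x$id, lineage = x$lineage_id, iteration = 1L,
               delta = x$energy$delta, dG = x$energy$dG,
               ddG = x$energy$ddG, recall = x$recall, clashes = 0L,
               sequence = x$sequence, stringsAsFactors = FALSE)))
  # 4. best design per lineage
  keep <- finals[!duplicated(vapply(finals, `[[`, numeric(1),
                                    "lineage_id"))]
  best <- finals[[1]]$energy$delta
  out <- list(final = keep,
              trace = list(list(
                iteration = 1L,
                pool_size_after_docking = config$r * config$d,
                pool_size_after_qc = n_surv,
                pool_size_after_design = config$k * length(selected),
                pool_size_after_design_qc = length(finals),
                selected_ids = vapply(keep, `[[`, character(1), "id"),
                best_delta_so_far = best)),
              ledger = ledger, best_delta = best, config = config)
  class(out) <- "nanoem_run"
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' Score a final candidate pool
#'
#' Per-candidate score table (sequence recovery over H3, global and
#' framework-anchored CDRH3 RMSD, TM-score, lDDT, DockQ, energies) plus a
#' mean +/- 95 percent CI-margin summary row and the pool success rate.
#' Structure-comparison fields are omitted when no reference truth is
#' available.
#'
#' @param final candidate list (from a `nanoem_run`).
#' @param reference_truth optional ground-truth `complex_model`.
#' @param cdrs `cdr_annotation` (needed for the H3 fields).
#' @return list with `scores` (data.frame), `summary` (mean and margin
#'   per metric), `success_rate` (NA when no ddG values are present).
#' @export
evaluate_run <- function(final, reference_truth = NULL, cdrs = NULL) {
  stopifnot(length(final) > 0)
  rows <- lapply(final, function(x) {
    row <- data.frame(id = x$id, dG = x$energy$dG, ddG = x$energy$ddG,
                      delta = x$energy$delta, clashes = 0L,
                      stringsAsFactors = FALSE)
    if (!is.null(reference_truth)) {
      stopifnot(!is.null(cdrs))
      nb_chain <- x$complex$nb_chain
      ref_nb <- subset_chains(reference_truth$structure,
                              reference_truth$nb_chain)
      pred_nb <- x$structure
      all_ids <- residue_ids(ref_nb)
      h3_ids <- cdr_residue_ids(ref_nb, reference_truth$nb_chain, cdrs,
                                "H3")
      ref_h3 <- paste(strsplit(extract_sequence(
        ref_nb, reference_truth$nb_chain), "")[[1]][
          match(h3_ids, all_ids)], collapse = "")
      pred_h3 <- paste(strsplit(x$sequence, "")[[1]][
        match(h3_ids, all_ids)], collapse = "")
      dq <- dockq(x$complex, reference_truth)
      row$aar_h3 <- aar(pred_h3, ref_h3)
      row$rmsd_global <- rmsd_region(pred_nb, ref_nb, all_ids, all_ids)
      row$rmsd_cdrh3 <- rmsd_region(pred_nb, ref_nb, h3_ids, all_ids)
      row$tm_score <- tm_score(pred_nb, ref_nb)
      row$lddt <- lddt(pred_nb, ref_nb)
      row$dockq <- dq$dockq
    }
    row
  })
  scores <- do.call(rbind, rows)
  num <- vapply(scores, is.numeric, logical(1)) & names(scores) != "clashes"
  summarize <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) return(c(mean = NA_real_, margin = NA_real_))
    c(mean = mean(v),
      margin = if (length(v) >= 2) ci_margin(v) else 0)
  }
  summ <- t(vapply(scores[num], summarize, numeric(2)))
  sr <- if (all(is.na(scores$ddG))) NA_real_ else
    success_rate(scores$ddG[!is.na(scores$ddG)])
  list(scores = scores, summary = as.data.frame(summ), success_rate = sr)
}

#' Paired EM-versus-linear synthetic benchmark
#'
#' Runs the EM pipeline and the linear baseline on the synthetic fixture
#' system with paired master seeds and reports, per replicate, the best
#' design delta of each arm and whether its best design improves on the
#' scaffold reference complex (ddG < 0). De novo mode; the scaffold
#' reference is the fixture complex carrying the original scaffold CDRH3.
#'
#' @param n_replicates number of paired replicates.
#' @param base_seed seed from which per-replicate master seeds derive.
#' @param r,d,n,k,iterations pipeline dimensions for the EM arm.
#' @param engines an `engine_suite`.
#' @return data.frame with one row per replicate: seeds, best deltas,
#'   ddG versus the scaffold reference, and success flags for both arms.
#' @export
benchmark_em_vs_linear <- function(n_replicates = 30, base_seed = 1,
                                   r = 4, d = 20, n = 4, k = 8,
                                   iterations = 6,
                                   engines = mock_engine_suite()) {
  scaffold <- fixture_nanobody()
  cdrs <- attr(scaffold, "cdrs")
  antigen <- fixture_antigen(seed = 1)
  epitope <- attr(antigen, "epitope")
  reference <- fixture_complex(seed = 1)
  dg_ref <- engines$energy$evaluate(reference)$dG
  rows <- lapply(seq_len(n_replicates), function(rep) {
    seed <- substream_seed(base_seed, "replicate", rep)
    cfg_em <- run_config(mode = "denovo", r = r, d = d, n = n, k = k,
                         iterations = iterations, seed = seed)
    cfg_lin <- run_config(mode = "denovo", r = r, d = d, n = n, k = k,
                          iterations = 1, seed = seed)
    em <- run_nanoem(cfg_em, scaffold, antigen, epitope, cdrs,
                     engines = engines)
    lin <- run_linear(cfg_lin, scaffold, antigen, epitope, cdrs,
                      engines = engines)
    data.frame(replicate = rep, seed = seed,
               em_best_delta = em$best_delta,
               lin_best_delta = lin$best_delta,
               em_ddg = em$best_delta - dg_ref,
               lin_ddg = lin$best_delta - dg_ref,
               em_success = em$best_delta - dg_ref < 0,
               lin_success = lin$best_delta - dg_ref < 0)
  })
  do.call(rbind, rows)
}
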