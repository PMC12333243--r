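#' Quantify intra- and inter-chain steric clashes
#'
#' An unordered atom pair clashes when its distance is below
#' `vdw_i + vdw_j - overlap_tolerance`. Atoms of the same residue are
#' exempt (covalently bonded), as are backbone-backbone pairs of residues
#' adjacent in the chain. A cell grid accelerates the search; the result
#' equals the quadratic all-pairs definition exactly.
#'
#' @param s a `nano_structure`.
#' @param overlap_tolerance allowed vdW overlap in Angstrom.
#' @return a `clash_report` with `intra_clashes`, `inter_clashes`,
#'   `pairs` (atom refs and distances) and `overlap_tolerance`.
#' @export
detect_clashes <- function(s, overlap_tolerance = 0.4) {
  stopifnot(inherits(s, "nano_structure"))
  a <- s$atoms
  chain_idx <- match(a$chain, unique(a$chain))
  cp <- clash_pairs_raw(s, overlap_tolerance)
  inter <- if (nrow(cp) > 0) chain_idx[cp$i] != chain_idx[cp$j] else logical(0)
  lab <- function(k) paste0(s$rid[k], ":", a$atom[k])
  pairs <- data.frame(
    atom_i = if (nrow(cp) > 0) lab(cp$i) else character(0),
    atom_j = if (nrow(cp) > 0) lab(cp$j) else character(0),
    i = cp$i, j = cp$j, distance = cp$dist, inter = inter,
    stringsAsFactors = FALSE)
  out <- list(intra_clashes = sum(!inter), inter_clashes = sum(inter),
              pairs = pairs, overlap_tolerance = overlap_tolerance)
  class(out) <- "clash_report"
  out
}

#' @export
print.clash_report <- function(x, ...) {
  cat("<clash_report> intra:", x$intra_clashes, " inter:", x$inter_clashes,
      " (tolerance ", x$overlap_tolerance, " A)\n", sep = "")
  invisible(x)
}

#' Total clash count of a report
#' @param report a `clash_report`.
#' @return integer count.
#' @export
n_clashes <- function(report) report$intra_clashes + report$inter_clashes

# lean internal path: raw clash pairs without report labelling, for the
# refinement loop and energy penalty where only indices/distances matter
clash_pairs_raw <- function(s, overlap_tolerance) {
  a <- s$atoms
  res_idx <- match(s$rid, unique(s$rid))
  chain_idx <- match(a$chain, unique(a$chain))
  backbone <- a$atom %in% BACKBONE_ATOMS
  .cpp_clash_pairs(coords(s), a$vdw, res_idx, chain_idx, backbone,
                   overlap_tolerance)
}

#' Soft-sphere refinement engine
#'
#' Gradient descent on a purely repulsive soft-sphere potential
#' `sum (d0 - d)^2` over clashing pairs (`d0` the clash threshold of the
#' pair), run until the structure is clash-free or `max_steps` is
#' exhausted. Bonded pairs are exempt from the potential, mirroring the
#' clash definition. This is the reference implementation of the
#' refinement contract; force-field engines can be plugged in behind the
#' same interface.
#'
#' @param step_size descent step scale.
#' @param overlap_tolerance clash tolerance in Angstrom.
#' @return a refinement engine (class `refinement_engine`).
#' @export
mock_minimizer <- function(step_size = 0.9, overlap_tolerance = 0.4) {
  eng <- list(kind = "refiner", name = "mock_minimizer",
              overlap_tolerance = overlap_tolerance)
  eng$refine <- function(s, max_steps = 200) {
    best <- s
    best_n <- nrow(clash_pairs_raw(s, overlap_tolerance))
    if (best_n == 0 || max_steps == 0) return(best)
    cur <- s
    vdw <- s$atoms$vdw
    for (step in seq_len(max_steps)) {
      p <- clash_pairs_raw(cur, overlap_tolerance)
      nc <- nrow(p)
      if (nc < best_n) { best <- cur; best_n <- nc }
      if (nc == 0) break
      m <- coords(cur)
      shift <- matrix(0, nrow(m), 3)
      for (k in seq_len(nc)) {
        i <- p$i[k]; j <- p$j[k]
        v <- m[j, ] - m[i, ]
        d <- sqrt(sum(v * v))
        if (d < 1e-8) {
          # coincident atoms: separate along a fixed axis
          v <- c(1, 0, 0); d <- 1
        }
        thr <- vdw[i] + vdw[j] - overlap_tolerance
        # overshoot the contact boundary slightly so resolved pairs do
        # not sit exactly on the clash threshold
        push <- step_size * (thr - p$dist[k] + 0.1) * v / d
        shift[i, ] <- shift[i, ] - push / 2
        shift[j, ] <- shift[j, ] + push / 2
      }
      cur <- set_coords(cur, m + shift)
    }
    if (nrow(clash_pairs_raw(cur, overlap_tolerance)) < best_n) best <- cur
    best
  }
  class(eng) <- c("mock_minimizer", "refinement_engine")
  eng
}

#' Refine a structure with a refinement engine
#'
#' The returned structure is guaranteed to have a clash count no larger
#' than the input's (the engine's best intermediate is kept otherwise).
#'
#' @param s a `nano_structure`.
#' @param engine a `refinement_engine` (see [mock_minimizer()]).
#' @param max_steps iteration budget; `0` returns the input unchanged.
#' @return a refined `nano_structure`.
#' @export
refine <- function(s, engine, max_steps = 200) {
  if (!inherits(engine, "refinement_engine"))
    stop("engine does not satisfy the refinement contract")
  out <- tryCatch(engine$refine(s, max_steps), error = function(e)
    stop("refinement engine '", engine$name, "' failed: ",
         conditionMessage(e)))
  out
}

#' Post-docking / post-design complex filters
#'
#' A complex is rejected when it still contains clashes after refinement,
#' when CDRH3 is not involved in the interface, or when none of the
#' desired epitope residues are part of the predicted interface. Reasons
#' accumulate; the outcome is deterministic and order-independent.
#'
#' @param complex a `complex_model`.
#' @param cdrs a `cdr_annotation` (unused directly; the H3 involvement is
#'   read from `iface`, which was computed with these annotations).
#' @param epitope the desired `epitope_spec`.
#' @param iface the `interface_map` of the refined complex.
#' @param clash the `clash_report` of the refined complex.
#' @return a `filter_outcome` with `passed` and `reasons`.
#' @export
apply_complex_filters <- function(complex, cdrs, epitope, iface, clash) {
  reasons <- character(0)
  if (n_clashes(clash) > 0)
    reasons <- c(reasons, "clash_after_refinement")
  if (length(iface$per_cdr_contacts$H3) == 0)
    reasons <- c(reasons, "cdrh3_not_in_interface")
  if (length(intersect(epitope$residues, iface$epitope_residues)) == 0)
    reasons <- c(reasons, "epitope_not_in_interface")
  out <- list(passed = length(reasons) == 0, reasons = reasons)
  class(out) <- "filter_outcome"
  out
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat("<filter_outcome>", if (x$passed) "passed" else
    paste("failed:", paste(x$reasons, collapse = ", ")), "\n")
  invisible(x)
}

#' Serialize QC results to JSON
#'
#' @param clash a `clash_report`.
#' @param outcome optional `filter_outcome`.
#' @return a JSON string.
#' @export
qc_to_json <- function(clash, outcome = NULL) {
  x <- list(intra_clashes = clash$intra_clashes,
            inter_clashes = clash$inter_clashes,
            overlap_tolerance = clash$overlap_tolerance,
            pairs = clash$pairs[, c("atom_i", "atom_j", "distance")])
  if (!is.null(outcome))
    x$filter <- list(passed = outcome$passed, reasons = outcome$reasons)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}
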