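#' Pair a nanobody pose with an antigen
#'
#' A complex is one structure holding the (posed) nanobody chain and the
#' antigen chain(s), plus provenance carried along the design pipeline.
#'
#' @param structure `nano_structure` containing all chains.
#' @param nb_chain the single nanobody chain id.
#' @param ag_chains antigen chain id(s).
#' @param lineage,iteration,engine_rank,engine_score optional provenance.
#' @return an object of class `complex_model`.
#' @export
complex_model <- function(structure, nb_chain, ag_chains,
                          lineage = NA_integer_, iteration = NA_integer_,
                          engine_rank = NA_integer_,
                          engine_score = NA_real_) {
  stopifnot(inherits(structure, "nano_structure"))
  ch <- chain_ids(structure)
  if (length(nb_chain) != 1 || !nb_chain %in% ch)
    stop("complex needs exactly one nanobody chain present in the structure")
  if (length(ag_chains) < 1 || !all(ag_chains %in% ch))
    stop("complex needs at least one antigen chain present in the structure")
  if (nb_chain %in% ag_chains)
    stop("nanobody chain cannot also be an antigen chain")
  out <- list(structure = structure, nb_chain = nb_chain,
              ag_chains = ag_chains, lineage = lineage,
              iteration = iteration, engine_rank = engine_rank,
              engine_score = engine_score)
  class(out) <- "complex_model"
  out
}

#' @export
print.complex_model <- function(x, ...) {
  cat("<complex_model> nb=", x$nb_chain, " ag=",
      paste(x$ag_chains, collapse = ","),
      if (!is.na(x$lineage)) paste0(" lineage=", x$lineage) else "",
      "\n", sep = "")
  invisible(x)
}

#' Specify a desired epitope
#'
#' @param residues character vector of antigen residue ids (see
#'   [res_id()]), or `NULL` to build them from `chain`/`resseq`/`icode`.
#' @param chain,resseq,icode vectors defining the residues when
#'   `residues` is `NULL`.
#' @param label free text.
#' @return an object of class `epitope_spec`.
#' @export
epitope_spec <- function(residues = NULL, chain = NULL, resseq = NULL,
                         icode = "", label = "") {
  if (is.null(residues)) residues <- res_id(chain, resseq, icode)
  residues <- unique(as.character(residues))
  if (length(residues) == 0) stop("epitope specification is empty")
  out <- list(residues = residues, label = label)
  class(out) <- "epitope_spec"
  out
}

# check an epitope resolves on the antigen chains of a structure
validate_epitope <- function(epitope, structure, ag_chains) {
  missing <- setdiff(epitope$residues, residue_ids(structure, ag_chains))
  if (length(missing) > 0)
    stop("epitope residues not found on the antigen: ",
         paste(utils::head(missing, 5), collapse = ","))
  invisible(epitope)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Quasi-uniform sphere sampling over radius (vdw + probe) with a
#' deterministic golden-spiral point set, so results are reproducible for
#' a given `n_points`.
#'
#' @param s a `nano_structure`.
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_points sphere-sampling count (>= 32).
#' @return a `sasa_result` with `per_atom` (A^2, one per atom),
#'   `per_residue` (named by residue id), `probe_radius`, `n_points`.
#' @export
shrake_rupley <- function(s, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(s, "nano_structure"))
  if (n_points < 32) stop("n_points must be >= 32")
  per_atom <- .cpp_sasa(coords(s), s$atoms$vdw, probe_radius,
                        as.integer(n_points))
  per_residue <- rowsum(per_atom, group = factor(s$rid, levels = unique(s$rid)))
  out <- list(per_atom = per_atom,
              per_residue = setNames(as.numeric(per_residue),
                                     rownames(per_residue)),
              probe_radius = probe_radius, n_points = as.integer(n_points))
  class(out) <- "sasa_result"
  out
}

#' Determine the binding interface of a complex by dSASA
#'
#' dSASA(residue) = SASA(residue in its isolated chain group) - SASA(in
#' the complex). Residues with dSASA above `dsasa_threshold` are interface
#' residues: antigen-side residues form the predicted epitope, nanobody
#' side the paratope. Antigen interface residues are then assigned to the
#' CDRs they interact with (any heavy-atom pair within `contact_cutoff`).
#' A dissociated pose simply yields empty sets.
#'
#' @param complex a `complex_model`.
#' @param cdrs a `cdr_annotation` on the nanobody chain.
#' @param dsasa_threshold burial threshold in A^2.
#' @param contact_cutoff heavy-atom contact distance in Angstrom for
#'   per-CDR assignment.
#' @param probe_radius,n_points SASA parameters (see [shrake_rupley()]).
#' @return an `interface_map` with `epitope_residues`,
#'   `paratope_residues`, `per_cdr_contacts` (list H1/H2/H3),
#'   `dsasa_threshold` and a per-residue `dsasa` table.
#' @export
compute_interface <- function(complex, cdrs, dsasa_threshold = 1.0,
                              contact_cutoff = 5.0, probe_radius = 1.4,
                              n_points = 960) {
  stopifnot(inherits(complex, "complex_model"))
  if (n_points < 32) stop("n_points must be >= 32")
  s <- complex$structure
  m <- coords(s)
  vdw <- s$atoms$vdw
  nb_rows <- which(s$atoms$chain == complex$nb_chain)
  ag_rows <- which(s$atoms$chain %in% complex$ag_chains)
  nb_ids <- unique(s$rid[nb_rows])
  ag_ids <- unique(s$rid[ag_rows])
  dsasa <- setNames(numeric(length(nb_ids) + length(ag_ids)),
                    c(nb_ids, ag_ids))
  # only residues with an atom within occlusion reach of the other chain
  # can have non-zero dSASA; everything else is exactly zero
  reach <- 2 * max(vdw) + 2 * probe_radius
  cp <- .cpp_close_pairs(m[nb_rows, , drop = FALSE],
                         m[ag_rows, , drop = FALSE], reach)
  active <- unique(c(s$rid[nb_rows[cp$i]], s$rid[ag_rows[cp$j]]))
  if (length(active) > 0) {
    act <- which(s$rid %in% active)
    cplx_area <- .cpp_sasa(m, vdw, probe_radius, as.integer(n_points), act)
    iso_area <- numeric(nrow(m))
    for (rows in list(nb_rows, ag_rows)) {
      sub_act <- match(intersect(act, rows), rows)
      iso_area[rows] <- .cpp_sasa(m[rows, , drop = FALSE], vdw[rows],
                                  probe_radius, as.integer(n_points),
                                  sub_act)
    }
    per_atom <- iso_area[act] - cplx_area[act]
    agg <- rowsum(per_atom, group = s$rid[act])
    dsasa[rownames(agg)] <- agg[, 1]
  }
  paratope <- nb_ids[dsasa[nb_ids] > dsasa_threshold]
  epitope <- ag_ids[dsasa[ag_ids] > dsasa_threshold]
  # per-CDR contacts: antigen interface residues with a heavy-atom pair
  # within contact_cutoff of that CDR's residues
  per_cdr <- list(H1 = character(0), H2 = character(0), H3 = character(0))
  if (length(epitope) > 0) {
    heavy <- s$atoms$element != "H"
    epi_rows <- heavy & s$rid %in% epitope
    epi_xyz <- as.matrix(s$atoms[epi_rows, c("x", "y", "z")])
    epi_rid <- s$rid[epi_rows]
    for (nm in names(per_cdr)) {
      crid <- cdr_residue_ids(s, complex$nb_chain, cdrs, nm)
      cdr_rows <- heavy & s$rid %in% crid
      if (!any(cdr_rows)) next
      cp <- .cpp_close_pairs(as.matrix(s$atoms[cdr_rows, c("x", "y", "z")]),
                             epi_xyz, contact_cutoff)
      if (nrow(cp) > 0)
        per_cdr[[nm]] <- intersect(epi_rid[unique(cp$j)], epitope)
    }
  }
  first <- !duplicated(s$rid)
  tab <- data.frame(chain = s$atoms$chain[first],
                    resseq = s$atoms$resseq[first],
                    icode = s$atoms$icode[first],
                    stringsAsFactors = FALSE)
  tab$dsasa <- as.numeric(dsasa[s$rid[first]])
  out <- list(epitope_residues = epitope, paratope_residues = paratope,
              per_cdr_contacts = per_cdr,
              dsasa_threshold = dsasa_threshold, dsasa = tab)
  class(out) <- "interface_map"
  out
}

#' @export
print.interface_map <- function(x, ...) {
  cat("<interface_map> epitope:", length(x$epitope_residues),
      "res; paratope:", length(x$paratope_residues), "res; H3 contacts:",
      length(x$per_cdr_contacts$H3), "\n")
  invisible(x)
}

#' Epitope recall of a docked pose
#'
#' The fraction of the desired epitope recovered in the predicted
#' interface: `|desired intersect predicted| / |desired|`.
#'
#' @param desired an `epitope_spec`.
#' @param predicted an `interface_map`.
#' @return a fraction in `[0, 1]`.
#' @export
epitope_recall <- function(desired, predicted) {
  stopifnot(inherits(desired, "epitope_spec"),
            inherits(predicted, "interface_map"))
  if (length(desired$residues) == 0) stop("desired epitope set is empty")
  length(intersect(desired$residues, predicted$epitope_residues)) /
    length(desired$residues)
}

#' Export per-residue dSASA as TSV
#'
#' @param iface an `interface_map`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dsasa_tsv <- function(iface, path) {
  utils::write.table(iface$dsasa, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize an interface map to JSON
#'
#' @param iface an `interface_map`.
#' @return a JSON string.
#' @export
interface_to_json <- function(iface) {
  jsonlite::toJSON(list(
    epitope_residues = iface$epitope_residues,
    paratope_residues = iface$paratope_residues,
    per_cdr_contacts = iface$per_cdr_contacts,
    dsasa_threshold = iface$dsasa_threshold), auto_unbox = TRUE)
}
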