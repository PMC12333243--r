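#' @name structure-model
#' @title Hierarchical structure model
#'
#' @description
#' Structures are stored as an atom table (one row per atom) grouped by
#' residue, in the spirit of bio3d's `pdb$atom`. Coordinates are in
#' Angstrom; residues are keyed by author numbering
#' `(chain, resseq, icode)`, with ranges inclusive on both ends. Van der
#' Waals radii come from a fixed element table (C 1.70, N 1.55, O 1.52,
#' S 1.80, H 1.20 A; 1.70 for anything else).
NULL

# 20 standard amino acids, three- and one-letter
AA_THREE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")
AA_ONE <- unname(AA_THREE)
AA_ONE_TO_THREE <- setNames(names(AA_THREE), AA_THREE)

# fixed vdw radius table (Angstrom)
VDW_TABLE <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
VDW_DEFAULT <- 1.70

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Van der Waals radius for an element symbol
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- VDW_TABLE[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# element symbol from a PDB atom name ("CA" -> "C", "OD1" -> "O", "1HB" -> "H")
element_from_name <- function(name) {
  e <- sub("^[0-9]*", "", toupper(name))
  substr(e, 1, 1)
}

#' Residue identifier strings
#'
#' Residues are referred to throughout the package by compact identifiers
#' of the form `"<chain><resseq><icode>"`, e.g. `"A10"` or `"H100A"`.
#'
#' @param chain chain id(s).
#' @param resseq author residue number(s).
#' @param icode insertion code(s), `""` when absent.
#' @return character vector of residue ids.
#' @export
res_id <- function(chain, resseq, icode = "") {
  paste0(chain, resseq, icode)
}

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resseq`, `icode`, `aa`
#'   (one-letter), `atom` (atom name, e.g. "CA"), `element`, `x`, `y`, `z`.
#'   A `vdw` column is derived from `element` when missing. Atoms of a
#'   residue must be contiguous rows.
#' @param name free-text identifier.
#' @param validate check model invariants (20-letter alphabet, CA present
#'   in every residue, unique residue ids per chain).
#' @return an object of class `nano_structure`.
#' @export
structure_model <- function(atoms, name = "structure", validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resseq", "icode", "aa", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  atoms$resseq <- as.integer(atoms$resseq)
  rid <- res_id(atoms$chain, atoms$resseq, atoms$icode)
  s <- list(name = name, atoms = atoms, rid = rid)
  class(s) <- "nano_structure"
  if (validate) validate_structure(s)
  s
}

validate_structure <- function(s) {
  a <- s$atoms
  if (!all(is.finite(c(a$x, a$y, a$z))))
    stop("non-finite atom coordinates")
  if (!all(a$vdw > 0)) stop("non-positive vdw radius")
  bad <- setdiff(unique(a$aa), AA_ONE)
  if (length(bad) > 0)
    stop("residue types outside the 20-letter alphabet: ",
         paste(bad, collapse = ","))
  rid <- s$rid
  first <- !duplicated(rid)
  # contiguity: each residue id appears in one run of rows
  if (any(duplicated(rid[first])))
    stop("atoms of a residue must be contiguous")
  has_ca <- tapply(a$atom == "CA", rid, any)
  if (!all(has_ca))
    stop("residues without a CA atom: ",
         paste(utils::head(names(has_ca)[!has_ca], 5), collapse = ","))
  invisible(s)
}

#' @export
print.nano_structure <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc) length(residue_ids(x, cc)), integer(1))
  cat("<nano_structure> ", x$name, "\n", sep = "")
  cat("  chains: ", paste0(ch, " (", nres, " res)", collapse = ", "),
      "; atoms: ", nrow(x$atoms), "\n", sep = "")
  invisible(x)
}

#' Chain identifiers, in file order
#' @param s a `nano_structure`.
#' @return character vector.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Residue identifiers of a structure
#' @param s a `nano_structure`.
#' @param chain optional chain id(s) to restrict to.
#' @return character vector of residue ids in order.
#' @export
residue_ids <- function(s, chain = NULL) {
  keep <- if (is.null(chain)) rep(TRUE, nrow(s$atoms)) else s$atoms$chain %in% chain
  unique(s$rid[keep])
}

#' Atom coordinate matrix
#' @param s a `nano_structure`.
#' @return numeric matrix, one row per atom, columns x,y,z.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

set_coords <- function(s, m) {
  s$atoms$x <- m[, 1]
  s$atoms$y <- m[, 2]
  s$atoms$z <- m[, 3]
  s
}

#' Subset a structure to chains
#' @param s a `nano_structure`.
#' @param chain chain id(s) to keep.
#' @return a `nano_structure`.
#' @export
subset_chains <- function(s, chain) {
  keep <- s$atoms$chain %in% chain
  if (!any(keep)) stop("no such chain: ", paste(chain, collapse = ","))
  structure_model(s$atoms[keep, , drop = FALSE], name = s$name,
                  validate = FALSE)
}

# subset to a set of residue ids (in structure order)
subset_residues <- function(s, rids) {
  keep <- s$rid %in% rids
  if (!any(keep)) stop("no atoms in the requested residues")
  structure_model(s$atoms[keep, , drop = FALSE], name = s$name,
                  validate = FALSE)
}

#' CA coordinates of a chain
#'
#' @param s a `nano_structure`.
#' @param chain optional chain id(s).
#' @return matrix of CA coordinates, rownames the residue ids, in order.
#' @export
ca_coords <- function(s, chain = NULL) {
  keep <- s$atoms$atom == "CA"
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  m <- as.matrix(s$atoms[keep, c("x", "y", "z")])
  rownames(m) <- s$rid[keep]
  m
}

#' Extract the one-letter sequence of a chain
#'
#' @param s a `nano_structure`.
#' @param chain_id chain label.
#' @return one-letter amino-acid string in residue order.
#' @export
extract_sequence <- function(s, chain_id) {
  keep <- s$atoms$chain == chain_id
  if (!any(keep)) stop("unknown chain: ", chain_id)
  first <- keep & !duplicated(s$rid)
  paste(s$atoms$aa[first], collapse = "")
}

# replace the sequence labels of a chain (used by threading engines)
set_sequence <- function(s, chain_id, sequence) {
  keep <- s$atoms$chain == chain_id
  rids <- unique(s$rid[keep])
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != length(rids))
    stop("sequence length ", length(aa), " != chain length ", length(rids))
  map <- setNames(aa, rids)
  s$atoms$aa[keep] <- unname(map[s$rid[keep]])
  s
}

#' Read a protein structure from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]. HETATM records and waters
#' are skipped; alternate locations are resolved to the highest occupancy
#' (ties broken by file order); author numbering is preserved.
#'
#' @param path path to a PDB file.
#' @param name structure name; defaults to the file name.
#' @return a `nano_structure`.
#' @export
read_pdb <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparseable PDB file: ", path,
                             " (", conditionMessage(e), ")"))
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$resid %in% names(AA_THREE), , drop = FALSE]
  if (nrow(a) == 0) stop("no standard protein residues in ", path)
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- "A"
  # altloc: keep the highest-occupancy copy of each (chain,resno,insert,elety)
  has_alt <- !is.na(a$alt) & a$alt != ""
  if (any(has_alt)) {
    occ <- ifelse(is.na(a$o), 1, a$o)
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -occ, seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety,
                             sep = "\r")), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- element_from_name(a$elety[bad])
  atoms <- data.frame(
    chain = a$chain, resseq = as.integer(a$resno), icode = a$insert,
    aa = unname(AA_THREE[a$resid]), atom = a$elety, element = elem,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  structure_model(atoms, name = name)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records via [bio3d::write.pdb()], with TER
#' between chains and END at the end; coordinates to three decimals.
#'
#' @param s a `nano_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "nano_structure"))
  a <- s$atoms
  if (nrow(a) == 0) stop("cannot serialize an empty structure")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resseq,
    resid = unname(AA_ONE_TO_THREE[a$aa]),
    eleno = seq_len(nrow(a)),
    elety = a$atom,
    chain = a$chain,
    insert = ifelse(a$icode == "", NA, a$icode),
    o = rep(1, nrow(a)), b = rep(0, nrow(a)),
    elesy = a$element,
    chainter = TRUE, end = TRUE)
  invisible(path)
}

#' Write chain sequences to a FASTA file
#'
#' @param s a `nano_structure`.
#' @param path output file path.
#' @param chains chains to export (default all).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(s, path, chains = chain_ids(s)) {
  lines <- unlist(lapply(chains, function(ch) {
    c(paste0(">", s$name, "_", ch), extract_sequence(s, ch))
  }))
  writeLines(lines, path)
  invisible(path)
}
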