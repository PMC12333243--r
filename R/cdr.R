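#' @name cdr-annotation
#' @title CDR annotation
#'
#' @description
#' CDR loops (H1/H2/H3) are stored as inclusive residue-number ranges on
#' the nanobody chain. Ranges are primarily user-supplied; a convenience
#' heuristic locates them by aligning the chain sequence to a built-in VHH
#' framework profile and mapping fixed IMGT-style windows, with the H3
#' bounds additionally anchored on the conserved Cys...Trp junction motif
#' of the FR3-FR4 boundary. Full HMM-based IMGT renumbering is not
#' implemented: downstream steps consume the positions, not the numbering.
NULL

# Built-in VHH framework profile. A generic camelid VHH sequence assembled
# from consensus framework segments; CDR windows (1-based positions in
# this profile) delimit the hypervariable loops. The conserved Cys sits at
# profile position 96 and the FR4 Trp at 103.
REF_VHH_FR1 <- "QVQLVESGGGLVQAGGSLRLSCAAS"   # 1-25
REF_VHH_H1  <- "GRTFSSYA"                    # 26-33
REF_VHH_FR2 <- "MGWFRQAPGKEREFVA"            # 34-49
REF_VHH_H2  <- "AISWSGGS"                    # 50-57
REF_VHH_FR3 <- "TYYADSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYC"  # 58-96
REF_VHH_H3  <- "ARDTAV"                      # 97-102
REF_VHH_FR4 <- "WGQGTQVTVSS"                 # 103-113
REF_VHH_SEQ <- paste0(REF_VHH_FR1, REF_VHH_H1, REF_VHH_FR2, REF_VHH_H2,
                      REF_VHH_FR3, REF_VHH_H3, REF_VHH_FR4)
REF_CDR_WINDOWS <- list(H1 = c(26L, 33L), H2 = c(50L, 57L),
                        H3 = c(97L, 102L))
REF_CYS_POS <- 96L
REF_TRP_POS <- 103L

#' Construct a CDR annotation
#'
#' @param cdr_ranges named list with elements `H1`, `H2`, `H3`, each an
#'   inclusive `c(start, end)` pair of author residue numbers on the
#'   nanobody chain.
#' @param scheme provenance tag, `"user"` or `"heuristic"`.
#' @return an object of class `cdr_annotation`.
#' @export
cdr_annotation <- function(cdr_ranges, scheme = c("user", "heuristic")) {
  scheme <- match.arg(scheme)
  need <- c("H1", "H2", "H3")
  if (!all(need %in% names(cdr_ranges)))
    stop("cdr_ranges must name H1, H2 and H3")
  cdr_ranges <- lapply(cdr_ranges[need], function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2])
      stop("each CDR range must be an inclusive c(start, end) pair")
    r
  })
  for (i in 1:2) {
    if (cdr_ranges[[i]][2] >= cdr_ranges[[i + 1]][1])
      stop("CDR ranges must be non-overlapping and ordered H1 < H2 < H3")
  }
  out <- list(cdr_ranges = cdr_ranges, scheme = scheme)
  class(out) <- "cdr_annotation"
  out
}

#' @export
print.cdr_annotation <- function(x, ...) {
  cat("<cdr_annotation> scheme=", x$scheme, "\n", sep = "")
  for (nm in names(x$cdr_ranges))
    cat("  ", nm, ": ", x$cdr_ranges[[nm]][1], "-", x$cdr_ranges[[nm]][2],
        "\n", sep = "")
  invisible(x)
}

#' Residue ids covered by a CDR range
#'
#' Residues between the range endpoints are taken in chain order, so
#' IMGT-style inserted residues (insertion codes) inside a range are
#' included, ordered by `(resseq, icode)` as they appear in the chain.
#'
#' @param s a `nano_structure`.
#' @param chain_id nanobody chain label.
#' @param cdrs a `cdr_annotation`.
#' @param which one of `"H1"`, `"H2"`, `"H3"`.
#' @return character vector of residue ids.
#' @export
cdr_residue_ids <- function(s, chain_id, cdrs, which = "H3") {
  rng <- cdrs$cdr_ranges[[which]]
  if (is.null(rng)) stop("no such CDR: ", which)
  keep <- s$atoms$chain == chain_id
  first <- keep & !duplicated(s$rid)
  resseq <- s$atoms$resseq[first]
  rids <- s$rid[first]
  i1 <- which(resseq == rng[1])[1]
  i2 <- rev(which(resseq == rng[2]))[1]
  if (is.na(i1) || is.na(i2))
    stop("CDR ", which, " range ", rng[1], "-", rng[2],
         " does not resolve on chain ", chain_id)
  rids[i1:i2]
}

# sequence positions (indices along the chain) of a CDR range
cdr_positions <- function(s, chain_id, cdrs, which = "H3") {
  rids <- residue_ids(s, chain_id)
  match(cdr_residue_ids(s, chain_id, cdrs, which), rids)
}

# map profile positions to query positions through a global alignment
profile_position_map <- function(query) {
  blosum <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = blosum)
  aln <- Biostrings::pairwiseAlignment(
    pattern = REF_VHH_SEQ, subject = query, type = "global",
    substitutionMatrix = blosum$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(REF_VHH_SEQ))
  pi <- 0L; qi <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (q[k] != "-") qi <- qi + 1L
    if (p[k] != "-" && q[k] != "-") map[pi] <- qi
  }
  map
}

#' Locate CDR ranges on a nanobody chain
#'
#' With `user_ranges` supplied, the ranges are validated against the chain
#' and returned unchanged (`scheme = "user"`). Otherwise a heuristic maps
#' the built-in VHH framework profile's CDR windows onto the chain via a
#' global BLOSUM62 alignment; the H3 range is bounded by the conserved
#' Cys(C)...Trp(W) motif of the FR3-FR4 junction (profile positions 96 and
#' 103), falling back to a direct motif scan when the aligned anchors do
#' not carry the expected residues.
#'
#' @param s nanobody `nano_structure`.
#' @param chain_id nanobody chain label.
#' @param user_ranges optional named list `list(H1=, H2=, H3=)` of
#'   inclusive `c(start, end)` author-number pairs.
#' @return a `cdr_annotation`.
#' @export
locate_cdrs <- function(s, chain_id, user_ranges = NULL) {
  rids <- residue_ids(s, chain_id)
  keep <- s$atoms$chain == chain_id & !duplicated(s$rid)
  resseq <- s$atoms$resseq[keep]
  if (!is.null(user_ranges)) {
    ann <- cdr_annotation(user_ranges, scheme = "user")
    for (nm in names(ann$cdr_ranges)) {
      rng <- ann$cdr_ranges[[nm]]
      if (!all(rng %in% resseq))
        stop("user CDR range ", nm, " (", rng[1], "-", rng[2],
             ") does not resolve to residues of chain ", chain_id)
    }
    return(ann)
  }
  if (length(rids) < 70)
    stop("heuristic CDR location needs a chain of >= 70 residues; ",
         "supply user_ranges")
  seqc <- extract_sequence(s, chain_id)
  map <- profile_position_map(seqc)
  aa <- strsplit(seqc, "")[[1]]
  pos_of <- function(p) map[p]
  h1 <- c(pos_of(REF_CDR_WINDOWS$H1[1]), pos_of(REF_CDR_WINDOWS$H1[2]))
  h2 <- c(pos_of(REF_CDR_WINDOWS$H2[1]), pos_of(REF_CDR_WINDOWS$H2[2]))
  cpos <- pos_of(REF_CYS_POS)
  wpos <- pos_of(REF_TRP_POS)
  anchors_ok <- !is.na(cpos) && !is.na(wpos) &&
    aa[cpos] == "C" && aa[wpos] == "W" && wpos - cpos >= 2
  if (!anchors_ok) {
    # motif fallback: last Cys in the chain, first Trp after it
    cys <- which(aa == "C")
    cpos <- if (length(cys) > 0) max(cys) else NA_integer_
    wpos <- if (!is.na(cpos)) {
      w <- which(aa == "W")
      w <- w[w > cpos + 1]
      if (length(w) > 0) min(w) else NA_integer_
    } else NA_integer_
  }
  if (is.na(cpos) || is.na(wpos) || wpos - cpos < 2)
    stop("could not locate the Cys...Trp FR3-FR4 junction motif; ",
         "supply user_ranges")
  if (anyNA(c(h1, h2)))
    stop("could not map the H1/H2 framework windows onto this chain; ",
         "supply user_ranges")
  ranges <- list(H1 = c(resseq[h1[1]], resseq[h1[2]]),
                 H2 = c(resseq[h2[1]], resseq[h2[2]]),
                 H3 = c(resseq[cpos + 1L], resseq[wpos - 1L]))
  cdr_annotation(ranges, scheme = "heuristic")
}
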