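#' Amino-acid recovery
#'
#' Fraction of positions at which two equal-length sequences carry the
#' same residue. No alignment is attempted.
#'
#' @param predicted,reference amino-acid strings of equal length.
#' @return fraction in `[0, 1]`.
#' @export
aar <- function(predicted, reference) {
  p <- strsplit(predicted, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  if (length(p) != length(r))
    stop("sequence lengths differ (", length(p), " vs ", length(r),
         "); AAR is defined for equal lengths only")
  mean(p == r)
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of `moving` onto `fixed`,
#' reflection-corrected so the rotation is proper (det = +1). The
#' rotation acts on row vectors from the right:
#' `moved = moving \%*\% rotation + translation`.
#'
#' @param moving,fixed numeric n x 3 coordinate matrices, n >= 3.
#' @return a `superposition` with `rotation`, `translation`, `rmsd`.
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("point counts differ")
  if (nrow(moving) < 3) stop("need at least 3 points")
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("non-finite coordinates")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  mc <- sweep(moving, 2, cm); fc <- sweep(fixed, 2, cf)
  h <- crossprod(mc, fc)
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- mc %*% rot
  rmsd <- sqrt(mean(rowSums((moved - fc)^2)))
  out <- list(rotation = rot, translation = as.numeric(cf - cm %*% rot),
              rmsd = rmsd)
  class(out) <- "superposition"
  out
}

#' Apply a superposition to coordinates
#' @param m an n x 3 coordinate matrix.
#' @param sp a `superposition` from [kabsch()].
#' @return the transformed n x 3 matrix.
#' @export
apply_superposition <- function(m, sp) {
  sweep(as.matrix(m) %*% sp$rotation, 2, sp$translation, `+`)
}

# CA coordinates for a residue-id set, erroring on residues without CA
ca_for_ids <- function(s, ids, what = "region") {
  m <- ca_coords(s)
  missing <- setdiff(ids, rownames(m))
  if (length(missing) > 0)
    stop("missing CA for ", what, " residues: ",
         paste(utils::head(missing, 10), collapse = ","))
  m[ids, , drop = FALSE]
}

#' Region CA RMSD after Kabsch alignment
#'
#' Superposes `pred` onto `ref` using the CA atoms of `align_on`, then
#' reports the CA RMSD over `region`. Global RMSD uses
#' `region = align_on =` the whole chain; the framework-anchored CDRH3
#' RMSD uses `region =` H3 with `align_on =` the whole chain.
#'
#' @param pred,ref `nano_structure`s with matching residue ids.
#' @param region residue ids the RMSD is reported over.
#' @param align_on residue ids the superposition is fitted on.
#' @return RMSD in Angstrom.
#' @export
rmsd_region <- function(pred, ref, region, align_on = region) {
  pa <- ca_for_ids(pred, align_on, "alignment")
  ra <- ca_for_ids(ref, align_on, "alignment")
  sp <- kabsch(pa, ra)
  pr <- apply_superposition(ca_for_ids(pred, region), sp)
  rr <- ca_for_ids(ref, region)
  sqrt(mean(rowSums((pr - rr)^2)))
}

# default residue correspondence: positional, over given chains
default_mapping <- function(pred, ref, chain = NULL) {
  p <- residue_ids(pred, chain)
  r <- residue_ids(ref, chain)
  if (length(p) != length(r))
    stop("structures have different residue counts; supply a mapping")
  data.frame(pred = p, ref = r, stringsAsFactors = FALSE)
}

#' TM-score
#'
#' Topological similarity `1/L_ref * sum 1/(1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8`, maximized over superpositions
#' found by deterministic iterative subset refinement seeded from the
#' whole-chain Kabsch fit.
#'
#' @param pred,ref `nano_structure`s.
#' @param mapping optional data.frame with columns `pred`, `ref` of
#'   corresponding residue ids; defaults to positional correspondence.
#' @param chain optional chain restriction for the default mapping.
#' @param superpose maximize over superpositions (the default); with
#'   `FALSE` the score is evaluated in the given coordinate frame, e.g.
#'   for a pose whose frame is already meaningful.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(pred, ref, mapping = NULL, chain = NULL,
                     superpose = TRUE) {
  if (is.null(mapping)) mapping <- default_mapping(pred, ref, chain)
  L <- nrow(mapping)
  if (L < 20) stop("TM-score needs at least 20 mapped residues")
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  p <- ca_for_ids(pred, mapping$pred)
  r <- ca_for_ids(ref, mapping$ref)
  score_of <- function(sp) {
    d <- sqrt(rowSums((apply_superposition(p, sp) - r)^2))
    mean(1 / (1 + (d / d0)^2))
  }
  if (!superpose) {
    d <- sqrt(rowSums((p - r)^2))
    return(mean(1 / (1 + (d / d0)^2)))
  }
  best <- -Inf
  for (cut in unique(c(d0, 2, 3.5, 5))) {
    sel <- seq_len(L)
    for (it in 1:20) {
      sp <- kabsch(p[sel, , drop = FALSE], r[sel, , drop = FALSE])
      best <- max(best, score_of(sp))
      d <- sqrt(rowSums((apply_superposition(p, sp) - r)^2))
      nsel <- which(d < cut)
      if (length(nsel) < 4 || identical(nsel, sel)) break
      sel <- nsel
    }
  }
  best
}

#' CA-based local distance difference test (lDDT)
#'
#' Superposition-free: over all reference CA pairs of distinct residues
#' within the inclusion radius, the fraction whose distance is preserved
#' in `pred` within each threshold, averaged over the thresholds.
#'
#' @param pred,ref `nano_structure`s.
#' @param mapping optional residue correspondence (see [tm_score()]).
#' @param chain optional chain restriction for the default mapping.
#' @param inclusion_radius reference-distance cutoff in Angstrom.
#' @param thresholds preservation thresholds in Angstrom.
#' @return lDDT in `[0, 1]`.
#' @export
lddt <- function(pred, ref, mapping = NULL, chain = NULL,
                 inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  if (is.null(mapping)) mapping <- default_mapping(pred, ref, chain)
  if (nrow(mapping) < 2) stop("lDDT needs at least 2 mapped residues")
  p <- ca_for_ids(pred, mapping$pred)
  r <- ca_for_ids(ref, mapping$ref)
  dr <- as.matrix(stats::dist(r))
  dp <- as.matrix(stats::dist(p))
  sel <- upper.tri(dr) & dr <= inclusion_radius
  if (!any(sel)) stop("no reference CA pairs within the inclusion radius")
  dev <- abs(dp[sel] - dr[sel])
  mean(vapply(thresholds, function(t) mean(dev <= t), numeric(1)))
}

#' DockQ complex quality score
#'
#' Combines interfacial contact preservation (fnat), ligand RMSD (LRMS,
#' nanobody CA after antigen superposition) and interface RMSD (iRMS,
#' backbone of the 10-Angstrom reference interface after interface
#' superposition):
#' `DockQ = (fnat + 1/(1+(iRMS/1.5)^2) + 1/(1+(LRMS/8.5)^2)) / 3`.
#'
#' @param pred,ref `complex_model`s with the same residue content; the
#'   nanobody is the ligand, the antigen the receptor.
#' @param contact_cutoff heavy-atom contact definition for fnat (A).
#' @param interface_cutoff contact definition for interface residues (A).
#' @return list with `fnat`, `lrms`, `irms`, `dockq`.
#' @export
dockq <- function(pred, ref, contact_cutoff = 5, interface_cutoff = 10) {
  stopifnot(inherits(pred, "complex_model"), inherits(ref, "complex_model"))
  contacts <- function(cx, cutoff) {
    s <- cx$structure
    heavy <- s$atoms$element != "H"
    nb_rows <- heavy & s$atoms$chain == cx$nb_chain
    ag_rows <- heavy & s$atoms$chain %in% cx$ag_chains
    cp <- .cpp_close_pairs(as.matrix(s$atoms[nb_rows, c("x", "y", "z")]),
                           as.matrix(s$atoms[ag_rows, c("x", "y", "z")]),
                           cutoff)
    nb_rid <- s$rid[nb_rows]; ag_rid <- s$rid[ag_rows]
    unique(paste(nb_rid[cp$i], ag_rid[cp$j], sep = "|"))
  }
  ref_contacts <- contacts(ref, contact_cutoff)
  if (length(ref_contacts) == 0)
    stop("reference complex has an empty interface")
  fnat <- length(intersect(ref_contacts, contacts(pred, contact_cutoff))) /
    length(ref_contacts)
  # LRMS: ligand CA RMSD after receptor superposition
  sp <- kabsch(ca_coords(pred$structure, pred$ag_chains),
               ca_coords(ref$structure, ref$ag_chains))
  pl <- apply_superposition(ca_coords(pred$structure, pred$nb_chain), sp)
  rl <- ca_coords(ref$structure, ref$nb_chain)
  lrms <- sqrt(mean(rowSums((pl - rl)^2)))
  # iRMS: backbone RMSD over the reference interface residues
  iface_pairs <- contacts(ref, interface_cutoff)
  iface_res <- unique(unlist(strsplit(iface_pairs, "|", fixed = TRUE)))
  bb <- function(cx) {
    s <- cx$structure
    rows <- s$rid %in% iface_res & s$atoms$atom %in% BACKBONE_ATOMS
    key <- paste(s$rid[rows], s$atoms$atom[rows])
    m <- as.matrix(s$atoms[rows, c("x", "y", "z")])
    rownames(m) <- key
    m[order(key), , drop = FALSE]
  }
  pb <- bb(pred); rb <- bb(ref)
  common <- intersect(rownames(pb), rownames(rb))
  spi <- kabsch(pb[common, , drop = FALSE], rb[common, , drop = FALSE])
  irms <- spi$rmsd
  dq <- (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
  list(fnat = fnat, lrms = lrms, irms = irms, dockq = dq)
}

#' Design success rate
#'
#' Percentage of designs with a negative relative binding free energy,
#' i.e. improved binding over the reference complex.
#'
#' @param ddg_values numeric vector of ddG values (kcal/mol).
#' @return percentage in `[0, 100]`.
#' @export
success_rate <- function(ddg_values) {
  if (length(ddg_values) == 0) stop("empty ddG list")
  100 * sum(ddg_values < 0) / length(ddg_values)
}

#' Margin of error of the 95 percent confidence interval
#'
#' Half the width of the 95 percent CI, `1.96 * sigma / sqrt(n)`. The
#' population standard deviation is used by default; set
#' `sd_type = "sample"` for the n-1 denominator.
#'
#' @param values numeric vector, length >= 2.
#' @param sd_type `"population"` or `"sample"`.
#' @return the half-width.
#' @export
ci_margin <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(values)
  if (n < 2) stop("ci_margin needs at least 2 values")
  sigma <- if (sd_type == "population")
    sqrt(mean((values - mean(values))^2)) else stats::sd(values)
  1.96 * sigma / sqrt(n)
}
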