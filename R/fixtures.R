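#' @name fixtures
#' @title Synthetic desk-scale fixtures
#'
#' @description
#' Deterministic toy structures that stand in for experimentally derived
#' inputs so the whole pipeline runs in seconds: a single-chain "nanobody"
#' with a serpentine-sheet framework and three protruding CDR loops (the
#' H3 flanked by the conserved Cys...Trp motif), a jittered-lattice
#' "antigen" slab with a designated surface epitope row, and a reference
#' docked complex with controllable planted clash content. All fixtures
#' are CA-trace models; the mock packer adds pseudo-CB atoms.
NULL

FIXTURE_NB_CHAIN <- "H"
FIXTURE_AG_CHAIN <- "A"

# CA-spacing constants of the toy geometry (Angstrom)
FX_CA_STEP <- 3.8      # along-row CA spacing of the framework sheet
FX_ROW_STEP <- 4.5     # row stacking distance
FX_LATTICE <- 4.5      # antigen lattice spacing

fixture_ca_atoms <- function(chain, resseq, aa, xyz) {
  data.frame(chain = chain, resseq = as.integer(resseq), icode = "",
             aa = aa, atom = "CA", element = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             vdw = vdw_radius("C"), stringsAsFactors = FALSE)
}

#' Synthetic nanobody scaffold
#'
#' 113 residues on chain H carrying the built-in VHH framework sequence
#' (CDR windows H1 26-33, H2 50-57, H3 97-102; Cys96...Trp103 junction).
#' Framework residues lie on a serpentine sheet in the y = 0 plane;
#' CDRH1/H2 sit as lateral bumps level with the sheet while CDRH3
#' protrudes below it as a shallow arc, forming the sole contact tip. Deterministic; the construction asserts a
#' clash-free trace.
#'
#' @return a `nano_structure` with a `cdrs` attribute holding the planted
#'   `cdr_annotation`.
#' @export
fixture_nanobody <- function() {
  seqc <- strsplit(REF_VHH_SEQ, "")[[1]]
  n <- length(seqc)
  windows <- REF_CDR_WINDOWS
  is_cdr <- rep(FALSE, n)
  for (w in windows) is_cdr[w[1]:w[2]] <- TRUE
  xyz <- matrix(0, n, 3)
  # framework: serpentine rows of 10 along x, stacked upward in z
  fw <- which(!is_cdr)
  per_row <- 10
  for (k in seq_along(fw)) {
    row <- (k - 1) %/% per_row
    col <- (k - 1) %% per_row
    if (row %% 2 == 1) col <- per_row - 1 - col
    xyz[fw[k], ] <- c(FX_CA_STEP * col, 0, 8 + FX_ROW_STEP * row)
  }
  # CDR loops: shallow arcs below the sheet; x-spacing of the H3 matches
  # the antigen lattice so the loop lies along a surface row when docked
  arc <- function(idx, xc, yc, depth, bow, step) {
    m <- length(idx)
    for (i in seq_len(m)) {
      th <- pi * i / (m + 1)
      xyz[idx[i], ] <<- c(xc + (i - (m + 1) / 2) * step, yc,
                          8 - depth + bow * (1 - sin(th)))
    }
  }
  arc(windows$H1[1]:windows$H1[2], xc = 4,  yc =  4.5, depth = -4, bow = 1,
      step = 3.4)
  arc(windows$H2[1]:windows$H2[2], xc = 18, yc = -4.5, depth = -4, bow = 1,
      step = 3.4)
  arc(windows$H3[1]:windows$H3[2], xc = 30, yc = 0,    depth = 9, bow = 1,
      step = FX_LATTICE)
  s <- structure_model(
    fixture_ca_atoms(FIXTURE_NB_CHAIN, seq_len(n), seqc, xyz),
    name = "fixture_nanobody")
  stopifnot(n_clashes(detect_clashes(s)) == 0)
  attr(s, "cdrs") <- cdr_annotation(windows, scheme = "user")
  s
}

#' Synthetic antigen with a planted surface epitope
#'
#' A jittered-lattice slab (default 6 x 5 x 2 sites at 4.5 A, 60
#' residues) on chain A. The designated epitope is the 6-residue top-edge
#' row (top layer, smallest y), fully solvent-exposed. Jitter is seeded
#' and small enough that the trace stays clash-free.
#'
#' @param seed jitter seed.
#' @param dims lattice dimensions `c(nx, ny, nz)`; `nx` is the epitope
#'   row length.
#' @param jitter uniform jitter half-width per coordinate (A).
#' @return a `nano_structure` with an `epitope` attribute (an
#'   `epitope_spec` naming the planted patch).
#' @export
fixture_antigen <- function(seed = 1, dims = c(6, 5, 2), jitter = 0.2) {
  if (any(dims < 1) || prod(dims) < 12)
    stop("antigen lattice must have at least 12 sites")
  grid <- expand.grid(ix = seq_len(dims[1]), iy = seq_len(dims[2]),
                      iz = seq_len(dims[3]))
  n <- nrow(grid)
  xyz <- FX_LATTICE * (as.matrix(grid) - 1)
  xyz <- xyz + with_seed(seed, matrix(runif(3 * n, -jitter, jitter), n, 3))
  aa <- AA_ONE[(seq_len(n) - 1) %% 20 + 1]
  s <- structure_model(
    fixture_ca_atoms(FIXTURE_AG_CHAIN, seq_len(n), aa, xyz),
    name = "fixture_antigen")
  stopifnot(n_clashes(detect_clashes(s)) == 0)
  epi <- which(grid$iz == dims[3] & grid$iy == 1)
  attr(s, "epitope") <- epitope_spec(
    residues = res_id(FIXTURE_AG_CHAIN, epi), label = "planted_top_edge_row")
  s
}

#' Synthetic docked complex
#'
#' Poses the fixture nanobody onto the planted epitope: the CDRH3 loop is
#' rotated 45 degrees about x so the framework points up and away, and
#' translated so each H3 residue sits at a diagonal offset (default
#' 3.6 A out, 3.6 A up) from the matching epitope-row residue. With the
#' defaults every H3 residue has epitope contacts, the pose is
#' clash-free, and the geometry keeps all CA pairs clear of the 8 A
#' energy-contact boundary so threading jitter cannot flip contact sets.
#' `clashes` plants that many isolated inter-chain clash pairs by moving
#' C-terminal framework residues next to far-face antigen atoms.
#'
#' @param seed antigen jitter seed.
#' @param clashes number of planted inter-chain clash pairs.
#' @param offset diagonal approach offset (A).
#' @return a `complex_model` with extra fields: `epitope`
#'   (`epitope_spec`), `cdrs` (`cdr_annotation`), `planted_clashes`
#'   (data.frame of planted pairs).
#' @export
fixture_complex <- function(seed = 1, clashes = 0, offset = 3.6) {
  nb <- fixture_nanobody()
  ag <- fixture_antigen(seed)
  cdrs <- attr(nb, "cdrs")
  epitope <- attr(ag, "epitope")
  h3_ids <- cdr_residue_ids(nb, FIXTURE_NB_CHAIN, cdrs, "H3")
  # rotate -45 deg about x: the local +z (framework) goes to (-y + z)/sqrt2,
  # pointing up and away from the antigen body, which occupies +y
  a <- -pi / 4
  rot <- matrix(c(1, 0, 0,
                  0, cos(a), sin(a),
                  0, -sin(a), cos(a)), 3, 3, byrow = TRUE)
  m <- coords(nb) %*% rot
  nb_r <- set_coords(nb, m)
  h3_c <- colMeans(ca_coords(nb_r)[h3_ids, , drop = FALSE])
  epi_ca <- ca_coords(ag)[epitope$residues, , drop = FALSE]
  target <- colMeans(epi_ca) + c(0, -offset, offset)
  nb_r <- set_coords(nb_r, sweep(m, 2, target - h3_c, `+`))
  planted <- data.frame(nb_res = character(0), ag_res = character(0))
  if (clashes > 0) {
    # far-face anchors: top layer, largest y, spaced two lattice steps
    agr <- ag$atoms
    anchor_ok <- agr$y > max(agr$y) - 1 & agr$z > max(agr$z) - 1
    anchors <- which(anchor_ok)[seq(1, by = 2, length.out = clashes)]
    if (anyNA(anchors)) stop("too many planted clashes requested")
    nres <- length(residue_ids(nb_r))
    for (k in seq_len(clashes)) {
      ares <- anchors[k]
      nb_res_idx <- nres - k + 1   # C-terminal framework tail
      rid <- residue_ids(nb_r)[nb_res_idx]
      rows <- which(nb_r$rid == rid)
      nb_r$atoms[rows, c("x", "y", "z")] <-
        rep(as.numeric(agr[ares, c("x", "y", "z")]) + c(0, 2.0, 0),
            each = length(rows))
      planted <- rbind(planted, data.frame(
        nb_res = rid, ag_res = res_id(FIXTURE_AG_CHAIN, agr$resseq[ares])))
    }
  }
  cx <- assemble_complex(nb_r, ag)
  cx$epitope <- epitope
  cx$cdrs <- cdrs
  cx$planted_clashes <- planted
  cx
}

#' Build a synthetic fixture
#'
#' Front door over [fixture_nanobody()], [fixture_antigen()] and
#' [fixture_complex()].
#'
#' @param kind one of `"nanobody"`, `"antigen"`, `"complex"`.
#' @param ... passed to the specific builder.
#' @return a `nano_structure` or `complex_model`.
#' @export
make_fixture <- function(kind = c("nanobody", "antigen", "complex"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         nanobody = fixture_nanobody(...),
         antigen = fixture_antigen(...),
         complex = fixture_complex(...))
}
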