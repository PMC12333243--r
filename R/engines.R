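#' @name engines
#' @title Engine contracts and mock reference engines
#'
#' @description
#' The five heavy stages of the pipeline -- structure prediction, docking,
#' CDR design, side-chain packing and binding-energy evaluation -- plus
#' refinement are pluggable contracts. The bundled mock engines are the
#' reference implementations: pure functions of their inputs and seed,
#' fast enough to exercise the whole method at desk scale. Adapters for
#' external tools can satisfy the same contracts.
NULL

#' Bundle engines into a suite
#'
#' Performs the capability handshake: every slot must carry the matching
#' contract class.
#'
#' @param predictor a `structure_predictor`.
#' @param docker a `docking_engine`.
#' @param designer a `cdr_designer`.
#' @param packer a `sidechain_packer`.
#' @param energy an `energy_model`.
#' @param refiner a `refinement_engine`.
#' @return an `engine_suite`.
#' @export
engine_suite <- function(predictor, docker, designer, packer, energy,
                         refiner) {
  chk <- function(x, cls, nm) {
    if (!inherits(x, cls))
      stop("engine '", nm, "' does not satisfy the ", cls, " contract")
  }
  chk(predictor, "structure_predictor", "predictor")
  chk(docker, "docking_engine", "docker")
  chk(designer, "cdr_designer", "designer")
  chk(packer, "sidechain_packer", "packer")
  chk(energy, "energy_model", "energy")
  chk(refiner, "refinement_engine", "refiner")
  out <- list(predictor = predictor, docker = docker, designer = designer,
              packer = packer, energy = energy, refiner = refiner)
  class(out) <- "engine_suite"
  out
}

#' The all-mock engine suite
#' @param ... passed on to the individual mock constructors is not
#'   supported; construct engines explicitly to customize.
#' @return an `engine_suite` of the mock reference engines.
#' @export
mock_engine_suite <- function(...) {
  engine_suite(predictor = mock_predictor(), docker = mock_docker(),
               designer = mock_designer(), packer = mock_packer(),
               energy = mock_energy(), refiner = mock_minimizer())
}

# --- structure predictor ----------------------------------------------------

# deterministic per-3-mer displacement in [-amp, amp]^3; the fractional
# parts of the integer code times three irrational-ish constants give a
# reproducible, platform-stable pseudo-random offset
trimer_disp <- function(code, amp) {
  u <- (code * c(0.6180339887498949, 0.7548776662466927,
                 0.5698402909980532)) %% 1
  amp * (2 * u - 1)
}

#' Mock structure predictor (sequence threading)
#'
#' Threads a sequence onto the template backbone and applies a
#' deterministic jitter to each CDR residue keyed by a hash of its local
#' 3-mer, so different CDR sequences yield different loop geometry,
#' reproducibly, while an unchanged sequence reproduces the template
#' coordinates exactly (the jitter is the difference between the new and
#' the template 3-mer offsets).
#'
#' @param jitter_amplitude maximum per-coordinate displacement (A).
#' @return a `structure_predictor`.
#' @export
mock_predictor <- function(jitter_amplitude = 0.15) {
  eng <- list(kind = "predictor", name = "mock_predictor",
              jitter_amplitude = jitter_amplitude)
  eng$predict <- function(sequence, template, cdrs,
                          chain_id = chain_ids(template)[1]) {
    rids <- residue_ids(template, chain_id)
    old <- strsplit(extract_sequence(template, chain_id), "")[[1]]
    new <- strsplit(sequence, "")[[1]]
    if (length(new) != length(old))
      stop("sequence length ", length(new),
           " does not match template chain length ", length(old))
    out <- set_sequence(template, chain_id, sequence)
    code3 <- function(aa, i) {
      n <- length(aa)
      c1 <- if (i > 1) match(aa[i - 1], AA_ONE) else 0L
      c2 <- match(aa[i], AA_ONE)
      c3 <- if (i < n) match(aa[i + 1], AA_ONE) else 0L
      (c1 * 441 + c2 * 21 + c3)
    }
    cdr_pos <- unlist(lapply(names(cdrs$cdr_ranges), function(nm)
      cdr_positions(template, chain_id, cdrs, nm)))
    m <- coords(out)
    for (i in cdr_pos) {
      disp <- trimer_disp(code3(new, i), jitter_amplitude) -
        trimer_disp(code3(old, i), jitter_amplitude)
      rows <- which(out$rid == rids[i])
      m[rows, ] <- sweep(m[rows, , drop = FALSE], 2, disp, `+`)
    }
    set_coords(out, m)
  }
  class(eng) <- c("mock_predictor", "structure_predictor")
  eng
}

# --- docking ----------------------------------------------------------------

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# proper rotation taking unit vector a to unit vector b (Rodrigues),
# acting on row vectors from the right
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to a
    p <- unit(if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    ax <- unit(c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
                 a[1] * p[2] - a[2] * p[1]))
    return(axis_angle(ax, pi))
  }
  k <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + k + k %*% k / (1 + cth)
}

# rotation about a unit axis by angle, acting on row vectors from the right
axis_angle <- function(axis, angle) {
  axis <- unit(axis)
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Mock docking engine
#'
#' Samples `d` rigid-body poses from a seeded generator. A configurable
#' fraction is biased by the provided restraints: the nanobody is oriented
#' so the CDRH3 centroid faces the epitope centroid and placed at contact
#' distance with rotational and translational noise; the remainder are
#' unrestrained random placements on the antigen surface. Poses are
#' scored by the negative epitope-paratope heavy-atom contact count and
#' returned sorted (lower score = more contacts = better).
#'
#' @param bias_fraction fraction of epitope-guided poses.
#' @param offset target CDRH3-to-epitope centroid distance (A).
#' @param noise translational noise s.d. (A).
#' @param tilt_sd angular noise s.d. (radians).
#' @param contact_cutoff heavy-atom contact distance for scoring (A).
#' @return a `docking_engine`.
#' @export
mock_docker <- function(bias_fraction = 0.8, offset = 4.5, noise = 1.0,
                        tilt_sd = 0.15, contact_cutoff = 5.0) {
  eng <- list(kind = "docker", name = "mock_docker",
              bias_fraction = bias_fraction)
  eng$dock <- function(nanobody, antigen, epitope, paratope_hint, d, seed) {
    if (d < 1) stop("d must be >= 1")
    validate_epitope(epitope, antigen, chain_ids(antigen))
    nb_chain <- chain_ids(nanobody)[1]
    nb_ca <- ca_coords(nanobody)
    h3_ids <- cdr_residue_ids(nanobody, nb_chain, paratope_hint, "H3")
    cdr_ids <- unlist(lapply(c("H1", "H2", "H3"), function(w)
      cdr_residue_ids(nanobody, nb_chain, paratope_hint, w)))
    ag_ca <- ca_coords(antigen)
    epi_ca <- ag_ca[epitope$residues, , drop = FALSE]
    epi_c <- colMeans(epi_ca)
    ag_c <- colMeans(ag_ca)
    normal <- unit(epi_c - ag_c)
    nb_c <- colMeans(nb_ca)
    h3_c <- colMeans(nb_ca[h3_ids, , drop = FALSE])
    approach <- unit(h3_c - nb_c)   # points from body to H3 tip
    m0 <- coords(nanobody)
    ag_radius <- max(sqrt(rowSums(sweep(ag_ca, 2, ag_c)^2)))
    heavy_cdr <- nanobody$atoms$element != "H" & nanobody$rid %in% cdr_ids
    epi_atoms_rows <- antigen$atoms$element != "H" &
      antigen$rid %in% epitope$residues
    epi_xyz <- as.matrix(antigen$atoms[epi_atoms_rows, c("x", "y", "z")])
    n_biased <- round(bias_fraction * d)
    poses <- with_seed(seed, lapply(seq_len(d), function(i) {
      if (i <= n_biased) {
        r0 <- rotation_between(approach, -normal)
        spin <- axis_angle(normal, runif(1, 0, 2 * pi))
        tilt_ax <- unit(rnorm(3))
        tilt <- axis_angle(tilt_ax, rnorm(1, 0, tilt_sd))
        rot <- r0 %*% spin %*% tilt
        target <- epi_c + offset * normal + rnorm(3, 0, noise)
      } else {
        rot <- random_rotation()
        dir <- unit(rnorm(3))
        target <- ag_c + (ag_radius + offset) * dir + rnorm(3, 0, noise)
      }
      # rotate about the nanobody centroid, then put H3 centroid on target
      mc <- sweep(m0, 2, nb_c) %*% rot
      shift <- target - colMeans(sweep(nb_ca[h3_ids, , drop = FALSE],
                                       2, nb_c) %*% rot)
      posed <- sweep(mc, 2, shift, `+`)
      nb_posed <- set_coords(nanobody, posed)
      score <- -nrow(.cpp_close_pairs(
        posed[heavy_cdr, , drop = FALSE], epi_xyz, contact_cutoff))
      list(rotation = rot,
           translation = as.numeric(shift - nb_c %*% rot),
           engine_score = score, nanobody = nb_posed)
    }))
    ord <- order(vapply(poses, `[[`, numeric(1), "engine_score"),
                 seq_along(poses))
    poses <- poses[ord]
    for (i in seq_along(poses)) {
      poses[[i]]$engine_rank <- i
      class(poses[[i]]) <- "dock_pose"
    }
    poses
  }
  class(eng) <- c("mock_docker", "docking_engine")
  eng
}

#' Combine a posed nanobody and an antigen into one complex
#'
#' @param nb_posed posed nanobody `nano_structure`.
#' @param antigen antigen `nano_structure`.
#' @param ... provenance fields passed to [complex_model()].
#' @return a `complex_model`.
#' @export
assemble_complex <- function(nb_posed, antigen, ...) {
  s <- structure_model(rbind(nb_posed$atoms, antigen$atoms),
                       name = paste0(nb_posed$name, "+", antigen$name),
                       validate = FALSE)
  complex_model(s, nb_chain = chain_ids(nb_posed)[1],
                ag_chains = chain_ids(antigen), ...)
}

# --- CDR design -------------------------------------------------------------

#' Mock CDR designer
#'
#' Proposes `k` candidates, each carrying 1-3 random substitutions
#' restricted to the selected CDR ranges; structures are re-threaded
#' through the predictor. Sequence outside the selected CDRs is untouched.
#'
#' @param max_substitutions upper bound on substitutions per candidate.
#' @return a `cdr_designer`.
#' @export
mock_designer <- function(max_substitutions = 3) {
  eng <- list(kind = "designer", name = "mock_designer")
  eng$design <- function(complex, cdrs, cdrs_to_design, k, seed, predictor) {
    if (k < 1) stop("k must be >= 1")
    if (length(cdrs_to_design) == 0) stop("empty CDR selection")
    nb <- subset_chains(complex$structure, complex$nb_chain)
    chain_id <- complex$nb_chain
    seqc <- extract_sequence(nb, chain_id)
    aa <- strsplit(seqc, "")[[1]]
    pos <- sort(unique(unlist(lapply(cdrs_to_design, function(w)
      cdr_positions(nb, chain_id, cdrs, w)))))
    with_seed(seed, lapply(seq_len(k), function(i) {
      nsub <- sample(seq_len(min(max_substitutions, length(pos))), 1)
      at <- sample(pos, nsub)
      new <- aa
      for (p in at) new[p] <- sample(setdiff(AA_ONE, aa[p]), 1)
      newseq <- paste(new, collapse = "")
      str <- predictor$predict(newseq, nb, cdrs, chain_id)
      list(sequence = newseq, structure = str,
           mutations = data.frame(pos = at, from = aa[at], to = new[at]))
    }))
  }
  class(eng) <- c("mock_designer", "cdr_designer")
  eng
}

# --- side-chain packing -----------------------------------------------------

#' Mock side-chain packer
#'
#' Leaves the backbone untouched and places an idealized pseudo-CB on
#' every non-glycine nanobody residue, 1.53 A from the CA along the local
#' chain binormal (recomputed from CA geometry, hence idempotent).
#' Glycines receive no CB.
#'
#' @return a `sidechain_packer`.
#' @export
mock_packer <- function() {
  eng <- list(kind = "packer", name = "mock_packer")
  eng$pack <- function(complex) {
    s <- complex$structure
    chain <- complex$nb_chain
    keep <- !(s$atoms$chain == chain & s$atoms$atom == "CB")
    a <- s$atoms[keep, , drop = FALSE]
    ca_rows <- which(a$chain == chain & a$atom == "CA")
    m <- as.matrix(a[ca_rows, c("x", "y", "z")])
    nres <- nrow(m)
    idx <- seq_len(nres)
    prev <- m[pmax(idx - 1, 1), , drop = FALSE]
    nxt <- m[pmin(idx + 1, nres), , drop = FALSE]
    t1 <- m - prev; t2 <- nxt - m
    bin <- cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
                 t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
                 t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])
    nrm <- sqrt(rowSums(bin^2))
    straight <- nrm < 0.1
    if (any(straight)) {
      # locally straight chain: fall back to a fixed perpendicular
      dirv <- nxt - prev
      alt <- cbind(dirv[, 2], -dirv[, 1], 0)
      use2 <- sqrt(rowSums(alt^2)) < 0.1
      alt[use2, ] <- cbind(0, dirv[, 3], -dirv[, 2])[use2, , drop = FALSE]
      bin[straight, ] <- alt[straight, , drop = FALSE]
      nrm <- sqrt(rowSums(bin^2))
    }
    cb <- m + 1.53 * bin / nrm
    gly <- a$aa[ca_rows] == "G"
    cbrow <- a[ca_rows[!gly], , drop = FALSE]
    cbrow$atom <- "CB"; cbrow$element <- "C"
    cbrow$vdw <- vdw_radius("C")
    cbrow[, c("x", "y", "z")] <- cb[!gly, , drop = FALSE]
    # interleave: each CB immediately after its CA
    new_a <- rbind(a, cbrow)
    ord <- order(c(seq_len(nrow(a)), ca_rows[!gly] + 0.5))
    out <- structure_model(new_a[ord, , drop = FALSE], name = s$name,
                           validate = FALSE)
    complex_model(out, complex$nb_chain, complex$ag_chains,
                  lineage = complex$lineage, iteration = complex$iteration,
                  engine_rank = complex$engine_rank,
                  engine_score = complex$engine_score)
  }
  class(eng) <- c("mock_packer", "sidechain_packer")
  eng
}

# --- binding energy ---------------------------------------------------------

# fixed alphabet permutation defining the planted complement
PLANTED_SHIFT <- 7L

#' Planted complement of an amino acid
#'
#' The mock energy table is built so that for an antigen residue `b`, the
#' uniquely optimal contacting nanobody residue is `planted_complement(b)`.
#'
#' @param aa one-letter amino acid(s).
#' @return one-letter amino acid(s).
#' @export
planted_complement <- function(aa) {
  AA_ONE[(match(aa, AA_ONE) - 1L + PLANTED_SHIFT) %% 20L + 1L]
}

#' The mock pairwise affinity table
#'
#' `m(a, b) = -5 + 0.25 * circdist(a, comp(b)) + 0.0005 * idx(a)`
#' (kcal/mol per contact), where `comp` is [planted_complement()] and
#' `circdist` the circular index distance on the 20-letter alphabet. The
#' tiny index term breaks ties so every argmin is strict. All entries are
#' negative: contacts are favorable, and the planted complement is the
#' unique best partner.
#'
#' @return a 20 x 20 matrix, rows the nanobody residue, columns the
#'   antigen residue.
#' @export
mock_energy_table <- function() {
  idx <- seq_len(20L)
  tab <- matrix(0, 20, 20, dimnames = list(AA_ONE, AA_ONE))
  for (b in idx) {
    comp <- (b - 1L + PLANTED_SHIFT) %% 20L + 1L
    dd <- abs(idx - comp)
    circ <- pmin(dd, 20L - dd)
    tab[, b] <- -5 + 0.25 * circ + 5e-4 * idx
  }
  tab
}

#' Mock binding-energy model
#'
#' dG is the sum over cross-chain residue contacts (CA-CA below the
#' cutoff) of the planted pairwise affinity table, plus a clash penalty;
#' ddG = dG(complex) - dG(reference) when a reference is given. Lower is
#' better for both. Separated chains score exactly zero.
#'
#' @param contact_cutoff CA-CA contact distance (A).
#' @param clash_penalty kcal/mol added per clashing atom pair.
#' @param overlap_tolerance clash tolerance (A).
#' @return an `energy_model`.
#' @export
mock_energy <- function(contact_cutoff = 8.0, clash_penalty = 1.0,
                        overlap_tolerance = 0.4) {
  tab <- mock_energy_table()
  eng <- list(kind = "energy", name = "mock_energy",
              contact_cutoff = contact_cutoff, table = tab)
  dg_of <- function(complex) {
    s <- complex$structure
    nb_ca <- ca_coords(s, complex$nb_chain)
    ag_ca <- ca_coords(s, complex$ag_chains)
    cp <- .cpp_close_pairs(nb_ca, ag_ca, contact_cutoff)
    e <- 0
    if (nrow(cp) > 0) {
      first <- !duplicated(s$rid)
      aa_of <- setNames(s$atoms$aa[first], s$rid[first])
      e <- sum(tab[cbind(aa_of[rownames(nb_ca)[cp$i]],
                         aa_of[rownames(ag_ca)[cp$j]])])
      e <- e + clash_penalty * nrow(clash_pairs_raw(s, overlap_tolerance))
    }
    e
  }
  eng$evaluate <- function(complex, reference = NULL) {
    dg <- dg_of(complex)
    if (!is.null(reference)) {
      ddg <- dg - dg_of(reference)
      out <- list(dG = dg, ddG = ddg, delta = ddg)
    } else {
      out <- list(dG = dg, ddG = NA_real_, delta = dg)
    }
    class(out) <- "energy_report"
    out
  }
  class(eng) <- c("mock_energy", "energy_model")
  eng
}
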