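# DNA-anchored constrained pairwise structural alignment.
#
# The optimal alignment of two HTH-DNA complexes minimizes the
# recognition-helix C-alpha RMSD subject to the DNA backbone-carbon RMSD
# being below a gate delta (default 2 A). Candidates are generated from
# 5-bp "canonical matching regions" around the basepair nearest the
# central residue: 5 regions per complex x 2 duplex orientations
# (mirror symmetry) = 50 candidates per pair. Correspondences are fully
# constrained (same atom type, sequential basepairs, 5'->3' preserved),
# so the constrained iterative-closest-points superposition reduces to a
# single closed-form least-squares step.

#' Basepair closest to the central residue
#'
#' Distance is from the central residue's C-alpha to the closer of the
#' two C1' atoms of each basepair; ties go to the lowest basepair index.
#'
#' @param cx an `hth_complex` with `central_residue` set.
#' @return 0-based basepair index.
#' @export
closest_basepair <- function(cx) {
  if (is.null(cx$central_residue)) stop("central residue is not set")
  ca <- protein_ca(cx)[as.character(cx$central_residue), ]
  L <- n_basepairs(cx)
  d <- vapply(0:(L - 1L), function(b) {
    min(sqrt(rowSums(sweep(bp_c1_coords(cx, b), 2, ca)^2)))
  }, numeric(1))
  which.min(d) - 1L
}

# Extract the backbone-carbon coordinates of a 5-bp region.
# Returns 25 x 3 matrices `fwd` and `rev`, rows ordered by (basepair
# ascending, atom name C1'..C5'); `rev` row k belongs to the partner
# nucleotide of the same basepair as `fwd` row k.
region_coords <- function(cx, start, span = 5L) {
  dx <- cx$duplex
  L <- n_basepairs(cx)
  pick <- function(strand, nt) {
    sub <- strand[strand$nt_index == nt, ]
    sub <- sub[match(BACKBONE_CARBONS, sub$atom), ]
    if (any(is.na(sub$x))) stop("missing backbone atom in nucleotide ", nt)
    as.matrix(sub[, c("x", "y", "z")])
  }
  fwd <- do.call(rbind, lapply(start:(start + span - 1L),
                               function(b) pick(dx$forward, b)))
  rev_ <- do.call(rbind, lapply(start:(start + span - 1L),
                                function(b) pick(dx$reverse, L - 1L - b)))
  structure(list(start = start, span = span, fwd = fwd, rev = rev_),
            class = "matching_region")
}

#' Canonical matching regions of a complex
#'
#' Five contiguous 5-bp regions, starting at n-4 through n where n is the
#' basepair closest to the central residue; every region contains n.
#'
#' @param cx an `hth_complex` with `central_residue` set.
#' @return list of 5 `matching_region` objects (with `n` in attribute
#'   `"anchor_bp"`).
#' @export
canonical_matching_regions <- function(cx) {
  n <- closest_basepair(cx)
  L <- n_basepairs(cx)
  if (n - 4L < 0L)
    stop("duplex too short on the 5' side: anchor basepair ", n,
         " needs 4 basepairs before it")
  if (n + 4L > L - 1L)
    stop("duplex too short on the 3' side: anchor basepair ", n,
         " needs 4 basepairs after it")
  regs <- lapply((n - 4L):n, function(s) region_coords(cx, s))
  attr(regs, "anchor_bp") <- n
  regs
}

#' Constrained atom correspondence between two matching regions
#'
#' FORWARD maps forward strand to forward strand, reverse to reverse,
#' basepair k to basepair k; FLIPPED (the duplex rotated 180 degrees
#' about its horizontal axis) maps forward to reverse with basepair order
#' reversed. Both preserve atom type and 5'->3' directionality.
#'
#' @param region_a,region_b `matching_region` objects.
#' @param orientation "FORWARD" or "FLIPPED".
#' @return list with 50 x 3 coordinate matrices `a` and `b` (row i of
#'   each corresponds) and a `pairs` data.frame annotating each pair
#'   (basepair offset within region, strand, atom name).
#' @export
region_correspondence <- function(region_a, region_b,
                                  orientation = c("FORWARD", "FLIPPED")) {
  orientation <- match.arg(orientation)
  span <- region_a$span
  natom <- length(BACKBONE_CARBONS)
  lab <- data.frame(
    bp = rep(0:(span - 1L), each = natom),
    atom = rep(BACKBONE_CARBONS, span))
  a <- rbind(region_a$fwd, region_a$rev)
  a_lab <- rbind(cbind(lab, strand = "F"), cbind(lab, strand = "R"))
  if (orientation == "FORWARD") {
    b <- rbind(region_b$fwd, region_b$rev)
    b_lab <- a_lab
  } else {
    # basepair k of a <-> basepair span-1-k of b; strands swapped
    perm <- as.vector(vapply(0:(span - 1L), function(k)
      (span - 1L - k) * natom + seq_len(natom), integer(natom)))
    b <- rbind(region_b$rev[perm, ], region_b$fwd[perm, ])
    b_lab <- rbind(cbind(lab[perm, ], strand = "R"),
                   cbind(lab[perm, ], strand = "F"))
  }
  list(a = a, b = b,
       pairs = data.frame(a_bp = a_lab$bp, a_strand = a_lab$strand,
                          a_atom = a_lab$atom, b_bp = b_lab$bp,
                          b_strand = b_lab$strand, b_atom = b_lab$atom))
}

#' Enumerate all candidate DNA-based alignments of a pair
#'
#' All region x region x orientation combinations, each superposed under
#' its constrained correspondence. Deterministically ordered by (region a
#' index, region b index, FORWARD before FLIPPED).
#'
#' @param cx_a,cx_b `hth_complex` objects with central residues set.
#' @return list of candidates: each has `region_a`, `region_b` (0-based
#'   region indices), `start_a`, `start_b` (basepair starts),
#'   `orientation`, `transform` (mapping b onto a) and `dna_rmsd`.
#' @export
enumerate_candidates <- function(cx_a, cx_b) {
  ra <- canonical_matching_regions(cx_a)
  rb <- canonical_matching_regions(cx_b)
  out <- list()
  for (i in seq_along(ra)) for (j in seq_along(rb))
    for (o in c("FORWARD", "FLIPPED")) {
      corr <- region_correspondence(ra[[i]], rb[[j]], o)
      sp <- superpose(corr$b, corr$a)
      out[[length(out) + 1L]] <- list(
        region_a = i - 1L, region_b = j - 1L,
        start_a = ra[[i]]$start, start_b = rb[[j]]$start,
        orientation = o, transform = sp$transform, dna_rmsd = sp$rmsd)
    }
  out
}

#' Gate candidates on DNA RMSD
#'
#' Keeps candidates with `dna_rmsd` strictly below `delta`.
#'
#' @param candidates list from [enumerate_candidates()].
#' @param delta DNA RMSD gate in Angstrom.
#' @return The surviving candidates (possibly an empty list).
#' @export
gate_candidates <- function(candidates, delta = hth_config()$delta) {
  Filter(function(c) c$dna_rmsd < delta, candidates)
}

#' Best recognition-helix residue mapping under a fixed transform
#'
#' Transforms helix b into a's frame with the DNA-derived transform (no
#' re-fitting), then minimizes the C-alpha RMSD over all admissible
#' residue mappings: every shift of one helix along the other with at
#' least `m` residues overlapping, in both N->C orientations. Ties break
#' toward the smaller |shift|, negative before positive, unflipped before
#' flipped.
#'
#' @param helix_a,helix_b C-alpha matrices (rownames = 0-based residue
#'   indices) of the two recognition helices.
#' @param transform `rigid_transform` mapping b's frame onto a's.
#' @param m minimum residue overlap (default 8).
#' @return list with `rmsd`, `residue_map` (matrix, columns `a`, `b`:
#'   0-based residue indices), `shift` and `flipped`.
#' @export
helix_rmsd_under_mapping <- function(helix_a, helix_b, transform,
                                     m = hth_config()$min_overlap) {
  la <- nrow(helix_a); lb <- nrow(helix_b)
  if (la < m || lb < m)
    stop("recognition helix shorter than the minimum overlap (", m, ")")
  bt <- transform_coords(transform, helix_b)
  ia <- as.integer(rownames(helix_a))
  ib <- as.integer(rownames(helix_b))
  shifts <- (-(lb - m)):(la - m)
  shifts <- shifts[order(abs(shifts), shifts)]
  best <- NULL
  for (flip in c(FALSE, TRUE)) {
    bord <- if (flip) lb:1 else 1:lb
    for (s in shifts) {
      i <- max(0L, s):(min(la, lb + s) - 1L)   # a positions (0-based)
      j <- i - s + 1L                          # index into bord
      rmsd <- coord_rmsd(helix_a[i + 1L, , drop = FALSE],
                         bt[bord[j], , drop = FALSE])
      if (is.null(best) || rmsd < best$rmsd - 1e-12)
        best <- list(rmsd = rmsd,
                     residue_map = cbind(a = ia[i + 1L], b = ib[bord[j]]),
                     shift = s, flipped = flip)
    }
  }
  best
}

helix_ca_matrix <- function(cx) {
  if (is.null(cx$recognition_helix)) stop("recognition helix is not set")
  idx <- cx$recognition_helix[1]:(cx$recognition_helix[2] - 1L)
  protein_ca(cx)[as.character(idx), , drop = FALSE]
}

#' Align a pair of HTH-DNA complexes
#'
#' Enumerates the 50 candidate DNA-based alignments, discards those with
#' DNA RMSD of `delta` or more, and among survivors returns the one
#' minimizing the recognition-helix RMSD. The returned transform maps
#' complex b onto complex a. The base-by-base correspondence extends the
#' winning 5-bp register arithmetically across the full overlap of both
#' duplexes, respecting orientation.
#'
#' @param cx_a,cx_b detected, standardized `hth_complex` objects.
#' @param delta DNA RMSD gate (Angstrom).
#' @param m minimum recognition-helix overlap (residues).
#' @return A `pairwise_alignment`: list with `transform`, `dna_rmsd`,
#'   `helix_rmsd`, `residue_map`, `basepair_map` (matrix, columns `a`,
#'   `b`), `orientation`, `delta`; or an `hth_unalignable` object when no
#'   candidate survives the gate.
#' @export
align_pair <- function(cx_a, cx_b, delta = hth_config()$delta,
                       m = hth_config()$min_overlap) {
  cands <- gate_candidates(enumerate_candidates(cx_a, cx_b), delta)
  if (length(cands) == 0L)
    return(structure(list(reason = sprintf(
      "no candidate alignment with DNA RMSD below %.2f A", delta)),
      class = "hth_unalignable"))
  ha <- helix_ca_matrix(cx_a); hb <- helix_ca_matrix(cx_b)
  best <- NULL
  for (cand in cands) {
    hm <- helix_rmsd_under_mapping(ha, hb, cand$transform, m)
    if (is.null(best) || hm$rmsd < best$helix_rmsd - 1e-12)
      best <- list(cand = cand, helix_rmsd = hm$rmsd, hm = hm)
  }
  cand <- best$cand
  La <- n_basepairs(cx_a); Lb <- n_basepairs(cx_b)
  if (cand$orientation == "FORWARD") {
    off <- cand$start_b - cand$start_a
    p <- max(0L, -off):min(La - 1L, Lb - 1L - off)
    bp_map <- cbind(a = p, b = p + off)
  } else {
    tot <- cand$start_a + cand$start_b + 4L
    p <- max(0L, tot - (Lb - 1L)):min(La - 1L, tot)
    bp_map <- cbind(a = p, b = tot - p)
  }
  structure(list(transform = cand$transform, dna_rmsd = cand$dna_rmsd,
                 helix_rmsd = best$helix_rmsd,
                 residue_map = best$hm$residue_map,
                 basepair_map = bp_map, orientation = cand$orientation,
                 region_a_start = cand$start_a,
                 region_b_start = cand$start_b,
                 helix_shift = best$hm$shift,
                 helix_flipped = best$hm$flipped, delta = delta),
            class = "pairwise_alignment")
}

#' Did a pairwise alignment fail the DNA gate?
#' @param x result of [align_pair()].
#' @return TRUE for an `hth_unalignable` result.
#' @export
is_unalignable <- function(x) inherits(x, "hth_unalignable")

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "<pairwise_alignment: DNA RMSD %.3f A, helix RMSD %.3f A, %s,\n  %d residue pairs, %d basepair pairs>\n",
    x$dna_rmsd, x$helix_rmsd, x$orientation, nrow(x$residue_map),
    nrow(x$basepair_map)))
  invisible(x)
}
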