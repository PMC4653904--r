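# Atomic contact statistics at the protein-DNA interface, reported in
# universal (exemplar-anchored) coordinates.

#' Atomic contacts of one complex in universal coordinates
#'
#' All protein-atom/DNA-atom pairs within `cutoff`, annotated with the
#' universal residue and basepair positions of the unified coordinate
#' system. Contacts at positions outside the mapped overlap are skipped;
#' their count is reported in the `"skipped_unmapped"` attribute. A
#' spatial cell grid (cell size = cutoff) restricts the pair search; the
#' result is identical to the full O(n m) scan.
#'
#' @param cx a member `hth_complex` (native frame; distances are
#'   rigid-motion invariant).
#' @param ucs an `hth_ucs` containing the complex.
#' @param cutoff contact distance threshold in Angstrom.
#' @param member_id the complex's id in the UCS (default: its
#'   `structure_id`).
#' @return data.frame with one row per contact: `protein_pos`,
#'   `dna_pos` (universal indices), `residue`, `protein_atom`, `base`,
#'   `dna_atom`, `distance`.
#' @export
atomic_contacts <- function(cx, ucs, cutoff = hth_config()$contact_cutoff,
                            member_id = cx$structure_id) {
  mem <- ucs$members[[member_id]]
  if (is.null(mem)) stop("complex ", member_id, " is not a UCS member")
  res_map <- mem$residue_map; bp_map <- mem$bp_map
  p <- cx$protein
  dx <- cx$duplex
  L <- n_basepairs(cx)
  d <- rbind(
    data.frame(bp = dx$forward$nt_index, base = dx$forward$base,
               atom = dx$forward$atom, x = dx$forward$x,
               y = dx$forward$y, z = dx$forward$z),
    data.frame(bp = L - 1L - dx$reverse$nt_index, base = dx$reverse$base,
               atom = dx$reverse$atom, x = dx$reverse$x,
               y = dx$reverse$y, z = dx$reverse$z))
  hits <- grid_contact_pairs(as.matrix(p[, c("x", "y", "z")]),
                             as.matrix(d[, c("x", "y", "z")]), cutoff)
  empty <- data.frame(protein_pos = integer(0), dna_pos = integer(0),
                      residue = character(0), protein_atom = character(0),
                      base = character(0), dna_atom = character(0),
                      distance = numeric(0))
  if (nrow(hits) == 0L) {
    attr(empty, "skipped_unmapped") <- 0L
    return(empty)
  }
  upos <- res_map[match(p$res_index[hits[, 1]], res_map[, "member"]),
                  "universal"]
  ubp <- bp_map[match(d$bp[hits[, 2]], bp_map[, "member"]), "universal"]
  mapped <- !is.na(upos) & !is.na(ubp)
  out <- data.frame(
    protein_pos = upos[mapped], dna_pos = ubp[mapped],
    residue = p$aa3[hits[mapped, 1]], protein_atom = p$atom[hits[mapped, 1]],
    base = d$base[hits[mapped, 2]], dna_atom = d$atom[hits[mapped, 2]],
    distance = hits[mapped, 3])
  attr(out, "skipped_unmapped") <- sum(!mapped)
  out
}

# Cell-grid neighbor search: returns matrix with columns (i, j, distance)
# for all pairs a[i,] x b[j,] within cutoff.
grid_contact_pairs <- function(a, b, cutoff) {
  if (cutoff <= 0 || nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(numeric(0), 0, 3))
  cell <- function(m) floor(sweep(m, 2, c(0, 0, 0)) / cutoff)
  ca <- cell(a); cb <- cell(b)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
  buckets <- split(seq_len(nrow(b)), keyb)
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    neigh <- as.vector(outer(
      outer(ca[i, 1] + (-1:1), ca[i, 2] + (-1:1), paste),
      ca[i, 3] + (-1:1), paste))
    js <- unlist(buckets[neigh], use.names = FALSE)
    if (is.null(js) || !length(js)) next
    dd <- sqrt(colSums((t(b[js, , drop = FALSE]) - a[i, ])^2))
    keep <- dd <= cutoff
    if (any(keep))
      out[[i]] <- cbind(i, js[keep], dd[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(numeric(0), 0, 3) else res
}

# Reference O(n*m) contact scan (used as an oracle in tests).
brute_contact_pairs <- function(a, b, cutoff) {
  if (cutoff <= 0 || nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(numeric(0), 0, 3))
  d <- cross_distances(a, b)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(matrix(numeric(0), 0, 3))
  cbind(hit[, 1], hit[, 2], d[hit])
}

#' Database-wide contact frequency table
#'
#' Aggregates [atomic_contacts()] over complexes: for every (universal
#' protein position, universal DNA position) pair, the total contact
#' count and the per-structure frequency (fraction of structures with at
#' least one contact at that pair).
#'
#' @param complexes named list of member complexes.
#' @param ucs an `hth_ucs`.
#' @param cutoff contact threshold in Angstrom.
#' @return data.frame with `protein_pos`, `dna_pos`, `count`,
#'   `n_structures`, `frequency`.
#' @export
contact_frequency_table <- function(complexes, ucs,
                                    cutoff = hth_config()$contact_cutoff) {
  ids <- names(complexes)
  n_str <- length(ids)
  tallies <- list()
  for (id in ids) {
    cc <- atomic_contacts(complexes[[id]], ucs, cutoff, member_id = id)
    if (nrow(cc) == 0L) next
    key <- paste(cc$protein_pos, cc$dna_pos)
    cnt <- table(key)
    for (k in names(cnt)) {
      if (is.null(tallies[[k]]))
        tallies[[k]] <- c(count = 0, structures = 0)
      tallies[[k]]["count"] <- tallies[[k]]["count"] + cnt[[k]]
      tallies[[k]]["structures"] <- tallies[[k]]["structures"] + 1
    }
  }
  if (length(tallies) == 0L)
    return(data.frame(protein_pos = integer(0), dna_pos = integer(0),
                      count = integer(0), n_structures = integer(0),
                      frequency = numeric(0)))
  pos <- do.call(rbind, strsplit(names(tallies), " "))
  out <- data.frame(
    protein_pos = as.integer(pos[, 1]), dna_pos = as.integer(pos[, 2]),
    count = vapply(tallies, function(t) unname(t["count"]), numeric(1)),
    n_structures = vapply(tallies, function(t) unname(t["structures"]),
                          numeric(1)))
  out$frequency <- out$n_structures / n_str
  rownames(out) <- NULL
  out[order(out$protein_pos, out$dna_pos), ]
}

# Fixed atom-type dictionary: every (residue, atom) and (base, atom)
# combination the model emits, in a deterministic documented order
# (residues as 3-letter codes, as they appear in contact records).
protein_atom_types <- function(atoms = c("CA", "CB")) {
  as.vector(outer(unname(AA1_TO_3), atoms, paste, sep = ":"))
}
dna_atom_types <- function() {
  as.vector(outer(paste0("D", NUCLEOTIDES), BACKBONE_CARBONS, paste,
                  sep = ":"))
}

#' Atom-type contact heatmap for one universal position pair
#'
#' Counts contacts at the given (protein position, DNA position) pair,
#' partitioned by (residue:atom) x (base:atom) type, over all member
#' complexes. Types are drawn from a fixed dictionary (20 amino acids x
#' emitted atom names; 4 bases x the five backbone carbons); unknown
#' names are binned as OTHER with a warning.
#'
#' @param complexes named list of member complexes.
#' @param ucs an `hth_ucs`.
#' @param protein_pos,dna_pos universal position pair.
#' @param cutoff contact threshold in Angstrom.
#' @return integer matrix (protein atom types x DNA atom types).
#' @export
atomtype_heatmap <- function(complexes, ucs, protein_pos, dna_pos,
                             cutoff = hth_config()$contact_cutoff) {
  ptypes <- c(protein_atom_types(), "OTHER")
  dtypes <- c(dna_atom_types(), "OTHER")
  H <- matrix(0L, length(ptypes), length(dtypes),
              dimnames = list(ptypes, dtypes))
  for (id in names(complexes)) {
    cc <- atomic_contacts(complexes[[id]], ucs, cutoff, member_id = id)
    cc <- cc[cc$protein_pos == protein_pos & cc$dna_pos == dna_pos, ,
             drop = FALSE]
    if (nrow(cc) == 0L) next
    pt <- paste(cc$residue, cc$protein_atom, sep = ":")
    dt <- paste0("D", cc$base, ":", cc$dna_atom)
    badp <- !(pt %in% ptypes); badd <- !(dt %in% dtypes)
    if (any(badp) || any(badd))
      warning("unknown atom name(s) binned as OTHER")
    pt[badp] <- "OTHER"; dt[badd] <- "OTHER"
    for (k in seq_along(pt)) H[pt[k], dt[k]] <- H[pt[k], dt[k]] + 1L
  }
  H
}
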