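# Domain model and PDB I/O.
#
# Internal conventions (used everywhere in the package):
#   * residue and basepair indices are 0-based, ranges are half-open
#     [start, end); PDB serial numbers appear only at the I/O boundary;
#   * a protein is a data.frame with one row per atom:
#       res_index, aa (1-letter), aa3, atom, element, x, y, z
#   * a DNA strand is a data.frame with one row per atom:
#       nt_index (0-based, 5'->3' along its own strand), base, atom,
#       element, x, y, z
#   * a standardized duplex pairs forward nucleotide i with reverse
#     nucleotide L-1-i (antiparallel, Watson-Crick complementary).

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")
AA1_TO_3 <- stats::setNames(names(AA3_TO_1), AA3_TO_1)

# Non-standard amino acids we still recognise as protein residues (so the
# pathology screen can flag them instead of silently dropping them).
NONSTANDARD_AA3 <- c("MSE", "SEC", "PYL", "MLY", "CSO", "PTR", "SEP",
                     "TPO", "HYP", "KCX", "CME", "CSD", "OCS", "ALY")

NT_RESID <- c(DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
              A = "A", C = "C", G = "G", T = "T", U = "U")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
BACKBONE_CARBONS <- c("C1'", "C2'", "C3'", "C4'", "C5'")

PATHOLOGY_FLAGS <- c("SINGLE_STRANDED_DNA", "MISSING_BACKBONE_ATOMS",
                     "NONSTANDARD_RESIDUES")

#' Construct a standardized DNA duplex
#'
#' @param forward,reverse strand data.frames (see package conventions);
#'   both ordered 5'->3' along their own strand.
#' @param pairs integer matrix with columns `fwd`, `rev` (0-based
#'   nucleotide indices); row i must pair forward i with reverse L-1-i.
#' @param validate check invariants (default TRUE).
#' @return An object of class `dna_duplex`.
#' @export
dna_duplex <- function(forward, reverse, pairs, validate = TRUE) {
  obj <- structure(list(forward = forward, reverse = reverse,
                        pairs = pairs), class = "dna_duplex")
  if (validate) validate_duplex(obj)
  obj
}

validate_duplex <- function(dx) {
  nf <- length(unique(dx$forward$nt_index))
  nr <- length(unique(dx$reverse$nt_index))
  if (nf != nr) stop("duplex strands differ in length (", nf, " vs ", nr, ")")
  L <- nf
  if (nrow(dx$pairs) != L) stop("pairs do not cover every basepair")
  if (!all(dx$pairs[, 1] == seq_len(L) - 1L) ||
      !all(dx$pairs[, 2] == rev(seq_len(L) - 1L)))
    stop("pairs are not the antiparallel bijection i <-> L-1-i")
  fb <- strand_bases(dx$forward); rb <- strand_bases(dx$reverse)
  if (!all(rb[L - dx$pairs[, 1]] == BASE_COMPLEMENT[fb[dx$pairs[, 1] + 1L]]))
    stop("paired bases are not Watson-Crick complementary")
  invisible(dx)
}

strand_bases <- function(strand) {
  idx <- sort(unique(strand$nt_index))
  vapply(idx, function(i) strand$base[strand$nt_index == i][1], character(1))
}

#' Number of basepairs in a duplex or complex
#' @param x a `dna_duplex` or `hth_complex`.
#' @return integer basepair count.
#' @export
n_basepairs <- function(x) {
  if (inherits(x, "hth_complex")) x <- x$duplex
  nrow(x$pairs)
}

#' Construct an HTH protein-DNA complex
#'
#' @param structure_id structure identifier (e.g. a PDB ID).
#' @param chain_id protein chain identifier.
#' @param protein protein atom data.frame (see package conventions).
#' @param duplex a `dna_duplex`.
#' @param resolution crystal resolution in Angstrom (`NA` if unknown).
#' @param recognition_helix optional half-open 0-based residue index range
#'   `c(start, end)` of the recognition helix.
#' @param central_residue optional 0-based index of the central residue
#'   (must lie inside `recognition_helix`).
#' @return An object of class `hth_complex`.
#' @export
hth_complex <- function(structure_id, chain_id, protein, duplex,
                        resolution = NA_real_, recognition_helix = NULL,
                        central_residue = NULL) {
  if (nrow(protein) == 0L) stop("complex must contain protein atoms")
  if (!inherits(duplex, "dna_duplex")) stop("duplex must be a dna_duplex")
  if (!is.null(recognition_helix)) {
    stopifnot(length(recognition_helix) == 2L,
              recognition_helix[1] < recognition_helix[2])
    if (!is.null(central_residue) &&
        (central_residue < recognition_helix[1] ||
         central_residue >= recognition_helix[2]))
      stop("central residue must lie inside the recognition helix")
  }
  structure(list(structure_id = structure_id, chain_id = chain_id,
                 resolution = resolution, protein = protein,
                 duplex = duplex,
                 recognition_helix = recognition_helix,
                 central_residue = central_residue),
            class = "hth_complex")
}

#' @export
print.hth_complex <- function(x, ...) {
  nres <- length(unique(x$protein$res_index))
  cat(sprintf("<hth_complex %s/%s: %d residues, %d bp%s>\n",
              x$structure_id, x$chain_id, nres, n_basepairs(x),
              if (is.null(x$recognition_helix)) "" else
                sprintf(", recognition helix [%d,%d) central %d",
                        x$recognition_helix[1], x$recognition_helix[2],
                        x$central_residue)))
  invisible(x)
}

# ---- accessors -------------------------------------------------------------

#' C-alpha coordinates of a complex's protein, ordered by residue index
#' @param cx an `hth_complex`.
#' @return matrix with one row per residue; rownames are residue indices.
#' @export
protein_ca <- function(cx) {
  ca <- cx$protein[cx$protein$atom == "CA", ]
  ca <- ca[order(ca$res_index), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$res_index
  m
}

residue_atom_coords <- function(cx, res_index) {
  sub <- cx$protein[cx$protein$res_index == res_index, ]
  if (nrow(sub) == 0L) stop("residue ", res_index, " has no atoms")
  as.matrix(sub[, c("x", "y", "z")])
}

# All DNA atoms of both strands as one coordinate matrix.
dna_atom_coords <- function(x) {
  dx <- if (inherits(x, "hth_complex")) x$duplex else x
  as.matrix(rbind(dx$forward[, c("x", "y", "z")],
                  dx$reverse[, c("x", "y", "z")]))
}

# C1' coordinates of basepair bp (forward nucleotide bp + its partner);
# returns a 2 x 3 matrix.
bp_c1_coords <- function(cx, bp) {
  dx <- cx$duplex
  L <- n_basepairs(cx)
  f <- dx$forward[dx$forward$nt_index == bp & dx$forward$atom == "C1'", ]
  r <- dx$reverse[dx$reverse$nt_index == (L - 1L - bp) &
                    dx$reverse$atom == "C1'", ]
  as.matrix(rbind(f[, c("x", "y", "z")], r[, c("x", "y", "z")]))
}

# Map a strand nucleotide to its basepair index.
nt_to_bp <- function(L, strand, nt_index) {
  if (strand == "forward") nt_index else L - 1L - nt_index
}

#' Apply a rigid transform to every atom of a complex
#' @param cx an `hth_complex`.
#' @param tr a `rigid_transform`.
#' @return The transformed complex.
#' @export
transform_complex <- function(cx, tr) {
  tx <- function(df) {
    if (nrow(df)) df[, c("x", "y", "z")] <-
        transform_coords(tr, as.matrix(df[, c("x", "y", "z")]))
    df
  }
  cx$protein <- tx(cx$protein)
  cx$duplex$forward <- tx(cx$duplex$forward)
  cx$duplex$reverse <- tx(cx$duplex$reverse)
  cx
}

#' Relabel the two DNA strands of a complex
#'
#' Swaps the forward and reverse strand labels (a pure relabeling: no atom
#' moves). Basepair index b becomes L-1-b.
#' @param cx an `hth_complex`.
#' @return The relabeled complex.
#' @export
flip_duplex <- function(cx) {
  dx <- cx$duplex
  cx$duplex <- dna_duplex(dx$reverse, dx$forward,
                          cbind(fwd = dx$pairs[, 1], rev = dx$pairs[, 2]))
  cx
}

# ---- reading ---------------------------------------------------------------

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (via bio3d), keeps the first alternate
#' location of each atom, strips waters and non-polymer heteroatoms, and
#' partitions chains into protein and nucleic by residue identity.
#' Non-standard amino acids are retained (so [screen_pathologies()] can
#' flag them); nucleotides are mapped to one-letter bases.
#'
#' @param x path to a PDB file, or a character vector of PDB text lines.
#' @return A raw structure of class `hth_raw`: list with `protein` and
#'   `dna`, each a named-by-chain list of atom data.frames, plus `helix`
#'   (HELIX record ranges per chain, if present).
#' @export
read_structure <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    path <- x
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(x, path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  at <- pdb$atom
  # first altloc only (decision: simplest deterministic rule)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at <- at[!duplicated(key), ]
  protein <- list(); dna <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, ]
    resid <- toupper(sub$resid)
    is_aa <- resid %in% c(names(AA3_TO_1), NONSTANDARD_AA3)
    is_nt <- resid %in% names(NT_RESID)
    if (any(is_aa)) {
      p <- sub[is_aa, ]
      rk <- paste(p$resno, p$insert)
      ridx <- as.integer(factor(rk, levels = unique(rk))) - 1L
      aa3 <- toupper(p$resid)
      protein[[ch]] <- data.frame(
        res_index = ridx,
        aa = ifelse(aa3 %in% names(AA3_TO_1), AA3_TO_1[aa3], "X"),
        aa3 = aa3, atom = p$elety,
        element = ifelse(is.na(p$elesy) | p$elesy == "",
                         substr(gsub("[^A-Za-z]", "", p$elety), 1, 1),
                         p$elesy),
        x = p$x, y = p$y, z = p$z, stringsAsFactors = FALSE)
    } else if (any(is_nt)) {
      n <- sub[is_nt, ]
      rk <- paste(n$resno, n$insert)
      nidx <- as.integer(factor(rk, levels = unique(rk))) - 1L
      dna[[ch]] <- data.frame(
        nt_index = nidx, base = unname(NT_RESID[toupper(n$resid)]),
        atom = n$elety,
        element = ifelse(is.na(n$elesy) | n$elesy == "",
                         substr(gsub("[^A-Za-z]", "", n$elety), 1, 1),
                         n$elesy),
        x = n$x, y = n$y, z = n$z, stringsAsFactors = FALSE)
    }
    # anything else (waters, ions, ligands) is stripped at read time
  }
  helix <- NULL
  if (!is.null(pdb$helix) && length(pdb$helix$start))
    helix <- data.frame(chain = pdb$helix$chain,
                        start = as.integer(pdb$helix$start),
                        end = as.integer(pdb$helix$end))
  structure(list(protein = protein, dna = dna, helix = helix),
            class = "hth_raw")
}

# ---- pathology screening ---------------------------------------------------

#' Screen a raw structure for the three structural pathologies
#'
#' A structure is admissible only when none of these hold:
#' \itemize{
#'   \item `SINGLE_STRANDED_DNA`: fewer than two nucleic chains;
#'   \item `MISSING_BACKBONE_ATOMS`: a protein residue without a C-alpha
#'     atom, or a nucleotide missing any of the five backbone carbons
#'     C1'-C5';
#'   \item `NONSTANDARD_RESIDUES`: a protein residue outside the 20
#'     standard amino acids.
#' }
#'
#' @param raw an `hth_raw` from [read_structure()].
#' @return An object of class `pathology_report`: list with `flags`
#'   (character subset of the three classes) and `details`.
#' @export
screen_pathologies <- function(raw) {
  stopifnot(inherits(raw, "hth_raw"))
  flags <- character(0); details <- list()
  if (length(raw$dna) < 2L) {
    flags <- c(flags, "SINGLE_STRANDED_DNA")
    details$dna_chains <- length(raw$dna)
  }
  missing <- character(0)
  for (ch in names(raw$protein)) {
    p <- raw$protein[[ch]]
    for (i in unique(p$res_index))
      if (!"CA" %in% p$atom[p$res_index == i])
        missing <- c(missing, sprintf("%s:res%d", ch, i))
  }
  for (ch in names(raw$dna)) {
    d <- raw$dna[[ch]]
    for (i in unique(d$nt_index))
      if (!all(BACKBONE_CARBONS %in% d$atom[d$nt_index == i]))
        missing <- c(missing, sprintf("%s:nt%d", ch, i))
  }
  if (length(missing)) {
    flags <- c(flags, "MISSING_BACKBONE_ATOMS")
    details$missing_backbone <- missing
  }
  nonstd <- character(0)
  for (ch in names(raw$protein)) {
    p <- raw$protein[[ch]]
    bad <- unique(p$aa3[!(p$aa3 %in% names(AA3_TO_1))])
    if (length(bad)) nonstd <- c(nonstd, sprintf("%s:%s", ch, bad))
  }
  if (length(nonstd)) {
    flags <- c(flags, "NONSTANDARD_RESIDUES")
    details$nonstandard <- nonstd
  }
  structure(list(flags = flags, details = details),
            class = "pathology_report")
}

#' Is a screened structure admissible?
#' @param report a `pathology_report`.
#' @return TRUE iff no pathology flag is set.
#' @export
is_admissible <- function(report) length(report$flags) == 0L

#' @export
print.pathology_report <- function(x, ...) {
  if (is_admissible(x)) cat("<pathology_report: admissible>\n")
  else cat("<pathology_report:", paste(x$flags, collapse = ", "), ">\n")
  invisible(x)
}

# ---- duplex standardization ------------------------------------------------

#' Standardize a DNA duplex
#'
#' Orders both strands 5'->3', pairs nucleotides geometrically
#' (Watson-Crick complementary bases whose C1'-C1' distance falls in
#' `config$pair_c1_range`, matched greedily by increasing distance),
#' removes unpaired terminal overhangs, and returns the paired duplex.
#' Coordinates are never altered; records are only reordered or removed.
#'
#' The first chain's given order is taken as its 5'->3' direction; the
#' second chain is reversed when the inferred pairing shows it was listed
#' antiparallel to convention.
#'
#' @param dna_chains named list of strand data.frames (from an `hth_raw`),
#'   or an `hth_raw`.
#' @param config an `hth_config`.
#' @return A `dna_duplex`.
#' @export
standardize_duplex <- function(dna_chains, config = hth_config()) {
  if (inherits(dna_chains, "hth_raw")) dna_chains <- dna_chains$dna
  if (inherits(dna_chains, "dna_duplex"))
    dna_chains <- list(F = dna_chains$forward, R = dna_chains$reverse)
  if (length(dna_chains) < 2L)
    stop("SINGLE_STRANDED_DNA: a duplex needs two nucleic chains")
  if (length(dna_chains) > 2L) {
    sizes <- vapply(dna_chains, function(d) length(unique(d$nt_index)),
                    integer(1))
    warning("more than two nucleic chains; keeping the two longest")
    dna_chains <- dna_chains[order(-sizes)[1:2]]
  }
  s1 <- dna_chains[[1]]; s2 <- dna_chains[[2]]
  b1 <- strand_bases(s1); b2 <- strand_bases(s2)
  if (!all(c(b1, b2) %in% names(BASE_COMPLEMENT)))
    stop("non-ACGT nucleotide in duplex: modified bases are not supported")
  c1 <- function(s) {
    sub <- s[s$atom == "C1'", ]
    sub <- sub[order(sub$nt_index), ]
    if (nrow(sub) != length(unique(s$nt_index)))
      stop("standardization error: a nucleotide lacks its C1' atom")
    as.matrix(sub[, c("x", "y", "z")])
  }
  d <- cross_distances(c1(s1), c1(s2))
  rng <- config$pair_c1_range
  comp_ok <- outer(b1, b2, function(a, b) BASE_COMPLEMENT[a] == b)
  cand <- which(comp_ok & d >= rng[1] & d <= rng[2], arr.ind = TRUE)
  if (nrow(cand) == 0L)
    stop("standardization error: no consistent basepairing found")
  cand <- cand[order(d[cand]), , drop = FALSE]
  used1 <- logical(length(b1)); used2 <- logical(length(b2))
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  if (nrow(pairs) < 2L)
    stop("standardization error: no consistent basepairing found")
  # orient second strand antiparallel to the first
  slope <- stats::cor(pairs[, 1], pairs[, 2])
  L2 <- length(b2)
  if (slope > 0) {
    s2 <- reverse_strand(s2, L2)
    pairs[, 2] <- L2 + 1L - pairs[, 2]
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  if (any(diff(pairs[, 2]) >= 0))
    stop("standardization error: basepairing is not antiparallel-monotonic")
  # remove unpaired nucleotides (overhangs) and renumber
  keep1 <- sort(pairs[, 1]); keep2 <- sort(pairs[, 2])
  f <- renumber_strand(s1, keep1)
  r <- renumber_strand(s2, keep2)
  L <- length(keep1)
  dna_duplex(f, r, cbind(fwd = 0:(L - 1L), rev = (L - 1L):0))
}

reverse_strand <- function(s, L = NULL) {
  if (is.null(L)) L <- length(unique(s$nt_index))
  # renumber so old last nucleotide becomes index 0; keep atom rows intact
  s$nt_index <- L - 1L - s$nt_index
  s[order(s$nt_index), ]
}

renumber_strand <- function(s, keep_1based) {
  old0 <- sort(unique(s$nt_index))[keep_1based]
  s <- s[s$nt_index %in% old0, ]
  s$nt_index <- match(s$nt_index, old0) - 1L
  s[order(s$nt_index), ]
}

# ---- domain splitting ------------------------------------------------------

#' Split a raw structure into per-domain complexes
#'
#' Given externally supplied HTH domain annotations (e.g. from detection,
#' or from generator ground truth), cuts each domain out of its chain(s),
#' merges multi-chain domains into one contiguously renumbered chain
#' (N->C in the order given), attaches the standardized cognate duplex,
#' and returns one complex per domain. Domains whose minimum atom distance
#' to the DNA exceeds `config$cognate_dna_cutoff` are excluded; reasons
#' are reported in the `"excluded"` attribute.
#'
#' @param raw an `hth_raw`.
#' @param domains list of domain annotations; each a list with `segments`
#'   (data.frame with columns `chain`, `start`, `end`: half-open 0-based
#'   residue ranges, concatenated in order), optional `structure_id`,
#'   `resolution`, `recognition_helix` and `central_residue` (both in the
#'   merged, renumbered domain coordinates).
#' @param config an `hth_config`.
#' @return list of `hth_complex` objects (attribute `excluded` lists
#'   dropped domains with reasons).
#' @export
split_domains <- function(raw, domains, config = hth_config()) {
  stopifnot(inherits(raw, "hth_raw"))
  duplex <- standardize_duplex(raw$dna, config)
  dna_xyz <- dna_atom_coords(duplex)
  out <- list(); excluded <- list()
  for (k in seq_along(domains)) {
    dom <- domains[[k]]
    seg <- dom$segments
    parts <- list()
    for (s in seq_len(nrow(seg))) {
      ch <- raw$protein[[seg$chain[s]]]
      if (is.null(ch)) stop("unknown protein chain: ", seg$chain[s])
      parts[[s]] <- ch[ch$res_index >= seg$start[s] &
                         ch$res_index < seg$end[s], ]
    }
    prot <- do.call(rbind, parts)
    if (nrow(prot) == 0L)
      stop("domain ", k, " selects no residues")
    # contiguous renumbering, N->C in the order supplied
    rk <- paste(rep(seq_len(nrow(seg)), vapply(parts, nrow, integer(1))),
                prot$res_index)
    prot$res_index <- as.integer(factor(rk, levels = unique(rk))) - 1L
    dmin <- min_cross_distance(as.matrix(prot[, c("x", "y", "z")]), dna_xyz)
    id <- if (!is.null(dom$structure_id)) dom$structure_id else
      sprintf("domain%d", k)
    if (dmin > config$cognate_dna_cutoff) {
      excluded[[id]] <- sprintf(
        "no cognate DNA within %.1f A (closest %.1f A)",
        config$cognate_dna_cutoff, dmin)
      next
    }
    out[[length(out) + 1L]] <- hth_complex(
      structure_id = id,
      chain_id = paste(unique(seg$chain), collapse = "+"),
      protein = prot, duplex = duplex,
      resolution = if (!is.null(dom$resolution)) dom$resolution else NA_real_,
      recognition_helix = dom$recognition_helix,
      central_residue = dom$central_residue)
  }
  attr(out, "excluded") <- excluded
  out
}

# ---- writing ---------------------------------------------------------------

#' Write a complex as PDB-format text
#'
#' Deterministic serialization: protein chain A first, then the forward
#' (chain B) and reverse (chain C) DNA strands, each 5'->3'. Residue and
#' nucleotide serial numbers are the internal 0-based indices plus one.
#'
#' @param cx an `hth_complex`.
#' @param path optional output file; when NULL the PDB text lines are
#'   returned instead.
#' @return `path` (invisibly) or a character vector of PDB lines.
#' @export
write_structure <- function(cx, path = NULL) {
  stopifnot(inherits(cx, "hth_complex"))
  if (nrow(cx$protein) == 0L) stop("refusing to write an empty protein")
  p <- cx$protein[order(cx$protein$res_index), ]
  f <- cx$duplex$forward[order(cx$duplex$forward$nt_index), ]
  r <- cx$duplex$reverse[order(cx$duplex$reverse$nt_index), ]
  blocks <- list(
    list(df = p, chain = "A", resid = unname(AA1_TO_3[p$aa]),
         resno = p$res_index + 1L),
    list(df = f, chain = "B", resid = paste0("D", f$base),
         resno = f$nt_index + 1L),
    list(df = r, chain = "C", resid = paste0("D", r$base),
         resno = r$nt_index + 1L))
  lines <- character(0); serial <- 0L
  for (b in blocks) {
    df <- b$df
    for (i in seq_len(nrow(df))) {
      serial <- serial + 1L
      nm <- df$atom[i]
      # PDB atom-name column alignment: 1-3 char names start in column 14
      nmfmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nmfmt, b$resid[i], b$chain, b$resno[i],
        df$x[i], df$y[i], df$z[i], 1, 0, df$element[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d", serial))
  }
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read, screen and standardize a single-domain complex
#'
#' Convenience wrapper: parses a PDB file/text, errors on any pathology,
#' merges all protein chains (in file order, contiguously renumbered) and
#' standardizes the duplex.
#'
#' @param x PDB path or text lines.
#' @param structure_id,chain_id,resolution metadata for the complex.
#' @param config an `hth_config`.
#' @return An `hth_complex`.
#' @export
read_complex <- function(x, structure_id = "complex", chain_id = "A",
                         resolution = NA_real_, config = hth_config()) {
  raw <- read_structure(x)
  rep <- screen_pathologies(raw)
  if (!is_admissible(rep))
    stop("structure is pathological: ", paste(rep$flags, collapse = ", "))
  prot <- do.call(rbind, lapply(seq_along(raw$protein), function(k) {
    p <- raw$protein[[k]]
    p$.chain_ord <- k
    p
  }))
  rk <- paste(prot$.chain_ord, prot$res_index)
  prot$res_index <- as.integer(factor(rk, levels = unique(rk))) - 1L
  prot$.chain_ord <- NULL
  hth_complex(structure_id, chain_id, prot,
              standardize_duplex(raw$dna, config), resolution = resolution)
}
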