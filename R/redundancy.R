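# Redundancy elimination on recognition-sequence identity under
# constrained shifts.

GAP <- "-"

#' Extract the 41-residue recognition sequence
#'
#' The amino-acid window extending 20 residues on each side of the
#' central residue (41 symbols total, central residue at 0-based offset
#' 20); chain positions outside the protein are padded with the GAP
#' symbol `-`.
#'
#' @param cx an `hth_complex` with `central_residue` set.
#' @return character vector of 41 one-letter codes / `-`, with attribute
#'   `central_offset = 20`.
#' @export
extract_recognition_sequence <- function(cx) {
  if (is.null(cx$central_residue)) stop("central residue is not set")
  ca <- cx$protein[cx$protein$atom == "CA", ]
  aa_by_index <- stats::setNames(ca$aa, ca$res_index)
  idx <- (cx$central_residue - 20L):(cx$central_residue + 20L)
  sym <- unname(aa_by_index[as.character(idx)])
  sym[is.na(sym)] <- GAP
  structure(sym, central_offset = 20L)
}

#' Minimum mismatch count over constrained shifts
#'
#' Slides sequence b relative to sequence a by every shift s with
#' |s| <= `max_shift` (which keeps the 11-residue window around both
#' central residues inside the overlap), counting mismatched positions
#' over the full overlap. A GAP aligned against an amino acid counts as a mismatch
#' (a truncated chain can never be identical to a longer one through its
#' padding); GAP-GAP columns match. Returns the minimum count and the
#' shift achieving it (ties: smallest |s|, negative before positive).
#'
#' @param a,b recognition sequences (length 41).
#' @param max_shift largest |shift| considered.
#' @return list with `mismatches` and `shift` (position i of a aligns
#'   with position i - shift of b).
#' @export
shifted_distance <- function(a, b, max_shift = hth_config()$max_shift) {
  stopifnot(length(a) == 41L, length(b) == 41L)
  n <- 41L
  shifts <- (-max_shift):max_shift
  shifts <- shifts[order(abs(shifts), shifts)]
  best <- NULL
  for (s in shifts) {
    ia <- max(0L, s):(min(n, n + s) - 1L)      # 0-based positions of a
    ib <- ia - s
    av <- a[ia + 1L]; bv <- b[ib + 1L]
    mm <- sum(av != bv)
    if (is.null(best) || mm < best$mismatches)
      best <- list(mismatches = mm, shift = s)
  }
  best
}

#' Build the redundancy graph
#'
#' Nodes are complexes; an edge joins two nodes exactly when the shifted
#' mismatch distance between their recognition sequences is zero.
#'
#' @param complexes named list of `hth_complex` objects with central
#'   residues set.
#' @param max_shift see [shifted_distance()].
#' @return An igraph undirected graph with vertex names = complex ids.
#' @export
build_redundancy_graph <- function(complexes,
                                   max_shift = hth_config()$max_shift) {
  ids <- names(complexes)
  if (is.null(ids))
    ids <- vapply(complexes, function(c) c$structure_id, character(1))
  seqs <- lapply(complexes, extract_recognition_sequence)
  n <- length(seqs)
  edges <- character(0)
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (shifted_distance(seqs[[i]], seqs[[j]], max_shift)$mismatches == 0L)
        edges <- c(edges, ids[i], ids[j])
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Select non-redundant representatives
#'
#' Every isolated node is retained. From each connected component of two
#' or more nodes, exactly one representative is kept: the node with the
#' largest degree (the most central), ties broken by best (lowest
#' Angstrom) resolution, then lexicographic id. Unknown resolutions sort
#' last. For a clique (all degrees equal) this reduces to keeping the
#' highest-resolution structure.
#'
#' @param graph redundancy graph from [build_redundancy_graph()].
#' @param resolutions named numeric vector of resolutions (Angstrom; `NA`
#'   allowed) covering every vertex.
#' @return character vector of retained complex ids (one per connected
#'   component), in vertex order.
#' @export
select_representatives <- function(graph, resolutions) {
  ids <- igraph::V(graph)$name
  comp <- igraph::components(graph)
  deg <- igraph::degree(graph)
  res <- resolutions[ids]
  res[is.na(res)] <- Inf  # unknown resolution sorts last
  retained <- character(0)
  for (k in seq_len(comp$no)) {
    members <- ids[comp$membership == k]
    o <- order(-deg[members], res[members], members)
    retained <- c(retained, members[o[1]])
  }
  retained[order(match(retained, ids))]
}

#' Eliminate redundant complexes
#'
#' Convenience wrapper: builds the redundancy graph and returns the
#' retained complexes.
#'
#' @param complexes named list of detected `hth_complex` objects.
#' @param max_shift see [shifted_distance()].
#' @return The retained sub-list (graph in attribute `"graph"`).
#' @export
eliminate_redundant <- function(complexes,
                                max_shift = hth_config()$max_shift) {
  g <- build_redundancy_graph(complexes, max_shift)
  res <- vapply(complexes, function(c)
    if (is.null(c$resolution)) NA_real_ else c$resolution, numeric(1))
  names(res) <- names(complexes)
  keep <- select_representatives(g, res)
  out <- complexes[keep]
  attr(out, "graph") <- g
  out
}
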