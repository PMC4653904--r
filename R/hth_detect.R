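# Heuristic HTH-domain detection.
#
# Three distance criteria, applied in order:
#   1. candidacy  : some alpha-helix has a contiguous 5-residue window
#                   whose mean residue-DNA distance is < 5 A;
#   2. orientation: each of those five residues lies within 6.5 A of DNA;
#   3. tri-helical: >= 3 helices are present and the central residue has a
#                   C-alpha within 18 A of at least one residue in two
#                   helices other than the recognition helix.
# Residue-DNA distance = the minimum over all residue atoms x DNA atoms.

#' Assign alpha-helical segments
#'
#' Uses HELIX-record annotations when supplied; otherwise a geometric
#' C-alpha rule: position i starts a helical turn when
#' \eqn{|CA_i - CA_{i+3}| \in [4.5, 6.5]} and
#' \eqn{|CA_i - CA_{i+4}| \in [5.5, 7.5]} Angstrom; residues covered by at
#' least one such turn are merged into maximal runs, and runs of at least
#' 4 residues are reported as segments.
#'
#' @param cx an `hth_complex` (or protein atom data.frame).
#' @param helix_ranges optional data.frame with half-open 0-based columns
#'   `start`, `end` taken as authoritative helix annotations.
#' @return data.frame with half-open 0-based columns `start`, `end` and
#'   `length`, ordered by `start`; zero rows when no helix is found.
#' @export
assign_helices <- function(cx, helix_ranges = NULL) {
  if (!is.null(helix_ranges)) {
    h <- helix_ranges[order(helix_ranges$start), , drop = FALSE]
    h$length <- h$end - h$start
    return(h[h$length >= 4L, c("start", "end", "length")])
  }
  ca <- if (inherits(cx, "hth_complex")) protein_ca(cx) else {
    sub <- cx[cx$atom == "CA", ]
    sub <- sub[order(sub$res_index), ]
    as.matrix(sub[, c("x", "y", "z")])
  }
  n <- nrow(ca)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0))
  if (n < 5L) return(empty)
  flagged <- logical(n - 4L)
  for (i in seq_len(n - 4L)) {
    d3 <- sqrt(sum((ca[i, ] - ca[i + 3L, ])^2))
    d4 <- sqrt(sum((ca[i, ] - ca[i + 4L, ])^2))
    flagged[i] <- d3 >= 4.5 && d3 <= 6.5 && d4 >= 5.5 && d4 <= 7.5
  }
  if (!any(flagged)) return(empty)
  # a run of turn starts f0..f1 spans residues f0..f1+4; overlapping or
  # touching spans merge into one segment
  r <- rle(flagged)
  rend <- cumsum(r$lengths); rstart <- rend - r$lengths + 1L
  spans <- cbind(rstart[r$values], rend[r$values] + 4L)  # 1-based incl.
  merged <- spans[1, , drop = FALSE]
  for (k in seq_len(nrow(spans))[-1]) {
    last <- nrow(merged)
    if (spans[k, 1] <= merged[last, 2])
      merged[last, 2] <- max(merged[last, 2], spans[k, 2])
    else merged <- rbind(merged, spans[k, ])
  }
  seg <- data.frame(start = merged[, 1] - 1L, end = merged[, 2],
                    length = merged[, 2] - merged[, 1] + 1L)
  seg[seg$length >= 4L, ]
}

#' Minimum distance between one residue and the DNA molecule
#'
#' The shortest pairwise distance over all atoms of the residue and all
#' atoms of the DNA.
#'
#' @param cx an `hth_complex`.
#' @param res_index 0-based residue index.
#' @return distance in Angstrom.
#' @export
residue_dna_distance <- function(cx, res_index) {
  min_cross_distance(residue_atom_coords(cx, res_index),
                     dna_atom_coords(cx))
}

# Per-residue DNA distances for a 0-based index vector.
residue_dna_distances <- function(cx, res_indices) {
  dna <- dna_atom_coords(cx)
  vapply(res_indices, function(i)
    min_cross_distance(residue_atom_coords(cx, i), dna), numeric(1))
}

#' Find the candidate recognition helix
#'
#' For every helix of at least `config$window` residues, locates the
#' contiguous window of that size minimizing the mean residue-DNA
#' distance (ties broken toward the lowest start index). The helix with
#' the smallest such mean qualifies when the mean is strictly below
#' `config$candidacy_cutoff`.
#'
#' @param cx an `hth_complex`.
#' @param helices segment data.frame from [assign_helices()].
#' @param config an `hth_config`.
#' @return NULL when no helix qualifies; otherwise a list with `helix`
#'   (half-open range), `window` (0-based indices of the five residues),
#'   `window_distances` and `mean_distance`.
#' @export
find_candidate_recognition_helix <- function(cx, helices,
                                             config = hth_config()) {
  w <- config$window
  best <- NULL
  for (h in seq_len(nrow(helices))) {
    idx <- helices$start[h]:(helices$end[h] - 1L)
    if (length(idx) < w) next
    d <- residue_dna_distances(cx, idx)
    means <- vapply(seq_len(length(idx) - w + 1L),
                    function(s) mean(d[s:(s + w - 1L)]), numeric(1))
    s <- which.min(means)  # which.min takes the first (lowest start) tie
    cand <- list(helix = c(helices$start[h], helices$end[h]),
                 window = idx[s:(s + w - 1L)],
                 window_distances = d[s:(s + w - 1L)],
                 mean_distance = means[s])
    if (is.null(best) || cand$mean_distance < best$mean_distance)
      best <- cand
  }
  if (is.null(best) || best$mean_distance >= config$candidacy_cutoff)
    return(NULL)
  best
}

#' Orientation criterion
#'
#' All five window residues must individually lie within
#' `config$orientation_cutoff` of the DNA (inclusive).
#'
#' @param window_distances the five residue-DNA distances of the
#'   candidacy window.
#' @param config an `hth_config`.
#' @return logical pass/fail.
#' @export
check_orientation <- function(window_distances, config = hth_config()) {
  all(window_distances <= config$orientation_cutoff)
}

#' Major axis of a DNA duplex
#'
#' Least-squares line through the centroid of the DNA backbone carbons
#' along the direction of maximal variance; the direction sign is
#' canonicalized toward increasing forward-strand nucleotide index.
#'
#' @param x a `dna_duplex` or `hth_complex`.
#' @return list with `point` and unit `direction`.
#' @export
dna_major_axis <- function(x) {
  dx <- if (inherits(x, "hth_complex")) x$duplex else x
  if (nrow(dx$pairs) < 2L) stop("major axis needs at least 2 basepairs")
  bb <- rbind(dx$forward[dx$forward$atom %in% BACKBONE_CARBONS, ],
              dx$reverse[dx$reverse$atom %in% BACKBONE_CARBONS, ])
  ax <- principal_axis(as.matrix(bb[, c("x", "y", "z")]))
  f <- dx$forward[dx$forward$atom == "C1'", ]
  f <- f[order(f$nt_index), ]
  proj <- as.matrix(f[, c("x", "y", "z")]) %*% ax$direction
  if (stats::cor(proj, seq_len(nrow(f))) < 0) ax$direction <- -ax$direction
  ax
}

#' Find the central residue of a recognition helix
#'
#' The helix residue whose C-alpha lies closest to the DNA major axis;
#' ties go to the lowest residue index.
#'
#' @param cx an `hth_complex`.
#' @param helix half-open 0-based range `c(start, end)`.
#' @return 0-based residue index.
#' @export
find_central_residue <- function(cx, helix) {
  ax <- dna_major_axis(cx)
  idx <- helix[1]:(helix[2] - 1L)
  ca <- protein_ca(cx)
  d <- point_line_distance(ca[as.character(idx), , drop = FALSE], ax)
  idx[which.min(d)]
}

#' Tri-helical bundle criterion
#'
#' Passes when at least three helices are assigned and at least two
#' helices other than the recognition helix contain a residue whose
#' C-alpha lies within `config$trihelical_cutoff` of the central
#' residue's C-alpha.
#'
#' @param cx an `hth_complex`.
#' @param helices segment data.frame.
#' @param helix the recognition helix (half-open range).
#' @param central 0-based central residue index.
#' @param config an `hth_config`.
#' @return list with `pass` and `neighbor_distances` (per other helix,
#'   the minimum C-alpha distance to the central residue).
#' @export
check_trihelical <- function(cx, helices, helix, central,
                             config = hth_config()) {
  ca <- protein_ca(cx)
  cca <- ca[as.character(central), ]
  others <- helices[!(helices$start == helix[1] & helices$end == helix[2]), ,
                    drop = FALSE]
  nd <- vapply(seq_len(nrow(others)), function(h) {
    idx <- others$start[h]:(others$end[h] - 1L)
    min(sqrt(rowSums(sweep(ca[as.character(idx), , drop = FALSE], 2,
                           cca)^2)))
  }, numeric(1))
  list(pass = nrow(helices) >= 3L &&
         sum(nd <= config$trihelical_cutoff) >= 2L,
       neighbor_distances = nd)
}

#' Detect an HTH domain
#'
#' Runs candidacy, orientation and tri-helical checks in order,
#' short-circuiting at the first failure.
#'
#' @param cx a standardized `hth_complex`.
#' @param config an `hth_config`.
#' @param helix_ranges optional authoritative helix annotations (see
#'   [assign_helices()]).
#' @return An `hth_assessment`: list with `verdict` ("pass"/"fail"),
#'   `failed_criterion` (NA, "candidacy", "orientation" or "trihelical"),
#'   `helices`, and when reached: `candidate_helix`, `closest_window`,
#'   `window_distances`, `mean_window_distance`, `central_residue`,
#'   `helix_neighbor_distances`.
#' @export
detect_hth <- function(cx, config = hth_config(), helix_ranges = NULL) {
  helices <- assign_helices(cx, helix_ranges)
  out <- list(verdict = "fail", failed_criterion = NA_character_,
              helices = helices, candidate_helix = NULL,
              closest_window = NULL, window_distances = NULL,
              mean_window_distance = NA_real_,
              central_residue = NA_integer_,
              helix_neighbor_distances = NULL)
  class(out) <- "hth_assessment"
  cand <- if (nrow(helices)) find_candidate_recognition_helix(cx, helices,
                                                              config)
  if (is.null(cand)) {
    out$failed_criterion <- "candidacy"
    return(out)
  }
  out$candidate_helix <- cand$helix
  out$closest_window <- cand$window
  out$window_distances <- cand$window_distances
  out$mean_window_distance <- cand$mean_distance
  if (!check_orientation(cand$window_distances, config)) {
    out$failed_criterion <- "orientation"
    return(out)
  }
  central <- find_central_residue(cx, cand$helix)
  out$central_residue <- central
  tri <- check_trihelical(cx, helices, cand$helix, central, config)
  out$helix_neighbor_distances <- tri$neighbor_distances
  if (!tri$pass) {
    out$failed_criterion <- "trihelical"
    return(out)
  }
  out$verdict <- "pass"
  out
}

#' @export
print.hth_assessment <- function(x, ...) {
  cat(sprintf("<hth_assessment: %s%s>\n", x$verdict,
              if (x$verdict == "fail")
                paste0(" at ", x$failed_criterion) else
                  sprintf(" (helix [%d,%d), central %d)",
                          x$candidate_helix[1], x$candidate_helix[2],
                          x$central_residue)))
  invisible(x)
}

#' Detect an HTH domain and annotate the complex
#'
#' Like [detect_hth()] but returns the complex with `recognition_helix`
#' and `central_residue` set; errors when detection fails.
#'
#' @inheritParams detect_hth
#' @return The annotated `hth_complex` (assessment in attribute
#'   `"assessment"`).
#' @export
detect_and_annotate <- function(cx, config = hth_config(),
                                helix_ranges = NULL) {
  a <- detect_hth(cx, config, helix_ranges)
  if (a$verdict != "pass")
    stop("no HTH domain detected (failed at ", a$failed_criterion, ")")
  cx$recognition_helix <- a$candidate_helix
  cx$central_residue <- a$central_residue
  attr(cx, "assessment") <- a
  cx
}
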