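# Shared fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_complex <- function(seed = 1L, ...) {
  key <- paste0("cx_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_hth_complex(synth_params(seed = seed, ...))
  .fixture_env[[key]]
}

# Shared atlas fixture: ten rigid copies of one complex plus one
# bent-DNA outlier, with their pairwise alignment distance matrix.
atlas_fixture <- function() {
  if (!is.null(.fixture_env$atlas)) return(.fixture_env$atlas)
  base <- make_hth_complex(synth_params(seed = 11))$complex
  cxs <- list(c1 = base)
  for (k in 2:10) {
    p <- perturb(base, random_rotation(seed = 100 + k),
                 c(k, -k, 2 * k))$complex
    p$structure_id <- paste0("c", k)
    cxs[[paste0("c", k)]] <- p
  }
  cxs$bent <- make_hth_complex(synth_params(seed = 11, bend_angle = 60),
                               structure_id = "bent")$complex
  D <- pairwise_distance_matrix(cxs)
  .fixture_env$atlas <- list(complexes = cxs, D = D)
  .fixture_env$atlas
}

# A UCS in which the given complex maps to itself by identity (for
# contact tests that need universal coordinates without a full atlas).
identity_ucs <- function(cx, id = cx$structure_id) {
  nres <- sort(unique(cx$protein$res_index))
  L <- n_basepairs(cx)
  members <- list()
  members[[id]] <- list(
    transform = rigid_transform(),
    residue_map = cbind(member = nres, universal = nres),
    bp_map = cbind(member = 0:(L - 1L), universal = 0:(L - 1L)),
    rmsd_to_exemplar = 0, aligned = cx)
  structure(list(exemplar_id = id, exemplar = cx, members = members,
                 outliers = list()), class = "hth_ucs")
}

random_recognition_sequence <- function(n_gap_head = 0L, n_gap_tail = 0L) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  s <- sample(aa, 41, replace = TRUE)
  if (n_gap_head > 0) s[seq_len(n_gap_head)] <- "-"
  if (n_gap_tail > 0) s[(41 - n_gap_tail + 1):41] <- "-"
  s[21] <- sample(aa, 1)  # central position is never GAP
  s
}

# Independent exhaustive-shift oracle for the recognition-sequence
# distance: plain double loop, no shared code with the implementation.
oracle_shift_distance <- function(a, b, max_shift = 15L) {
  best <- Inf
  for (s in (-max_shift):max_shift) {
    mm <- 0L
    for (i in 0:40) {
      j <- i - s
      if (j >= 0 && j <= 40 && a[i + 1] != b[j + 1]) mm <- mm + 1L
    }
    best <- min(best, mm)
  }
  as.integer(best)
}

# Independent exhaustive enumeration of recognition-helix mappings.
oracle_helix_rmsd <- function(ha, hb_transformed, m = 8L) {
  la <- nrow(ha); lb <- nrow(hb_transformed)
  best <- Inf
  for (flip in c(FALSE, TRUE)) {
    B <- if (flip) hb_transformed[lb:1, , drop = FALSE] else hb_transformed
    for (s in -(lb):la) {
      pairs <- NULL
      for (i in 0:(la - 1)) {
        j <- i - s
        if (j >= 0 && j <= lb - 1) pairs <- rbind(pairs, c(i + 1, j + 1))
      }
      if (is.null(pairs) || nrow(pairs) < m) next
      d2 <- rowSums((ha[pairs[, 1], , drop = FALSE] -
                       B[pairs[, 2], , drop = FALSE])^2)
      best <- min(best, sqrt(mean(d2)))
    }
  }
  best
}

# Independent O(n*m) contact oracle.
oracle_contacts <- function(a, b, cutoff) {
  hits <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d <= cutoff) hits <- rbind(hits, c(i, j, d))
  }
  if (is.null(hits)) matrix(numeric(0), 0, 3) else hits
}
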