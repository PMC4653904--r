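# Position weight matrices from curated binding sites, mapped onto
# structure basepair positions.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Read a binding-site table
#'
#' TSV with columns `complex_id`, `sequence`, `source`,
#' `experiment_type`, `quality`, `provenance_id` (the latter two may be
#' empty). Sequences are upper-cased and checked against A/C/G/T.
#'
#' @param path TSV file path.
#' @return data.frame of binding sites.
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("complex_id", "sequence", "source", "experiment_type",
              "quality", "provenance_id")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("sites table lacks column(s): ", paste(missing, collapse = ", "))
  df$sequence <- toupper(df$sequence)
  bad <- !grepl("^[ACGT]+$", df$sequence)
  if (any(bad))
    stop("invalid binding-site sequence(s): row ",
         paste(which(bad), collapse = ", "))
  df
}

#' Remove duplicate binding-site records
#'
#' Keeps at most one site per (provenance id, sequence): the same
#' experiment reported by several repositories collapses to one record.
#' Sites lacking a provenance id are always kept, as are distinct
#' experiments reporting the same sequence.
#'
#' @param sites binding-site data.frame.
#' @return The deduplicated data.frame.
#' @export
dedupe_sites <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  prov <- sites$provenance_id
  has_prov <- !is.na(prov) & prov != ""
  key <- paste(prov, sites$sequence, sep = "|")
  drop <- has_prov & duplicated(key)
  sites[!drop, , drop = FALSE]
}

reverse_complement <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

#' Align binding sites to a reference sequence
#'
#' Places each site ungapped on the reference (the crystal duplex
#' forward-strand sequence) at the offset and strand (forward or
#' reverse-complement) maximizing the number of matching bases. Ties go
#' to the forward strand, then the smallest offset. Sites longer than the
#' reference are trimmed to its length with a warning.
#'
#' @param sites binding-site data.frame (or character vector of
#'   sequences).
#' @param reference reference sequence string.
#' @return An aligned block: character matrix (sites x reference
#'   positions) with `NA` outside each site; attributes `offset` and
#'   `strand` record each placement.
#' @export
align_sites <- function(sites, reference) {
  seqs <- if (is.data.frame(sites)) sites$sequence else sites
  reference <- toupper(reference)
  Lr <- nchar(reference)
  ref <- strsplit(reference, "")[[1]]
  block <- matrix(NA_character_, length(seqs), Lr)
  offs <- integer(length(seqs)); strands <- character(length(seqs))
  for (k in seq_along(seqs)) {
    s <- toupper(seqs[k])
    if (nchar(s) > Lr) {
      warning("site ", k, " longer than reference (", nchar(s), " > ",
              Lr, "): trimmed")
      s <- substr(s, 1, Lr)
    }
    cand <- c(forward = s, reverse = reverse_complement(s))
    Ls <- nchar(s)
    best <- NULL
    for (st in names(cand)) {
      cc <- strsplit(cand[[st]], "")[[1]]
      for (off in 0:(Lr - Ls)) {
        score <- sum(cc == ref[(off + 1):(off + Ls)])
        if (is.null(best) || score > best$score)
          best <- list(score = score, off = off, strand = st, chars = cc)
      }
    }
    block[k, (best$off + 1):(best$off + nchar(s))] <- best$chars
    offs[k] <- best$off; strands[k] <- best$strand
  }
  structure(block, offset = offs, strand = strands, reference = reference)
}

#' Build a PWM from an aligned site block
#'
#' Column with nucleotide counts c and total N gets probabilities
#' `(c + alpha) / (N + 4 alpha)` (Laplace smoothing); a column with no
#' data is the uniform non-informative prior (0.25 each).
#'
#' @param block aligned character matrix from [align_sites()] (NA =
#'   absent).
#' @param alpha Laplace pseudocount (default 1).
#' @return A `pwm`: 4 x L numeric matrix (rows A, C, G, T; columns sum to
#'   1) with per-column observation counts in attribute `support`.
#' @export
build_pwm <- function(block, alpha = hth_config()$alpha) {
  L <- ncol(block)
  mat <- matrix(NA_real_, 4, L, dimnames = list(NUCLEOTIDES, NULL))
  support <- integer(L)
  for (j in seq_len(L)) {
    col <- block[, j]
    col <- col[!is.na(col)]
    cnt <- table(factor(col, levels = NUCLEOTIDES))
    N <- sum(cnt)
    support[j] <- N
    mat[, j] <- if (N == 0L) rep(0.25, 4) else
      (as.numeric(cnt) + alpha) / (N + 4 * alpha)
  }
  structure(mat, support = support, class = c("pwm", "matrix", "array"))
}

#' Write / read a PWM matrix text file
#'
#' 4 tab-separated rows labeled A/C/G/T, one column per position.
#' @param pwm a `pwm`.
#' @param path file path.
#' @return `path` invisibly (write) / a `pwm` (read).
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(base = rownames(pwm), unclass(pwm))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1])
  dimnames(mat) <- list(df[[1]], NULL)
  stopifnot(identical(rownames(mat), NUCLEOTIDES))
  structure(mat, support = rep(NA_integer_, ncol(mat)),
            class = c("pwm", "matrix", "array"))
}

#' Map PWM columns onto structure basepair positions
#'
#' Column i corresponds to basepair `offset + i` under forward
#' orientation, or `offset + L - 1 - i` with complement-swapped columns
#' under reverse orientation. Basepairs without a column carry the
#' uniform prior.
#'
#' @param pwm a `pwm` of length L.
#' @param cx an `hth_complex`.
#' @param offset 0-based basepair offset of PWM column 0.
#' @param orientation "forward" or "reverse".
#' @return A `structure_pwm_map`: list with `map` (matrix, columns
#'   `column`, `bp`), `orientation`, and `bp_distributions` (4 x
#'   n_basepairs matrix over the whole duplex, uniform where unmapped).
#' @export
map_pwm_to_structure <- function(pwm, cx, offset = 0L,
                                 orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  L <- ncol(pwm)
  nbp <- n_basepairs(cx)
  cols <- 0:(L - 1L)
  bp <- if (orientation == "forward") offset + cols
        else offset + L - 1L - cols
  keep <- bp >= 0L & bp < nbp
  dist <- matrix(0.25, 4, nbp, dimnames = list(NUCLEOTIDES, NULL))
  vals <- unclass(pwm)
  if (orientation == "reverse")
    vals <- vals[c("T", "G", "C", "A"), , drop = FALSE]  # complement swap
  rownames(vals) <- NUCLEOTIDES
  dist[, bp[keep] + 1L] <- vals[, which(keep)]
  structure(list(map = cbind(column = cols[keep], bp = bp[keep]),
                 orientation = orientation, bp_distributions = dist),
            class = "structure_pwm_map")
}

#' Build the PWM of a complex from its binding sites
#'
#' Convenience pipeline: dedupe, align to the complex's forward-strand
#' duplex sequence, smooth, and map onto basepairs.
#'
#' @param sites binding-site data.frame (rows for this complex).
#' @param cx an `hth_complex`.
#' @param alpha Laplace pseudocount.
#' @return list with `pwm` and `map` (a `structure_pwm_map`).
#' @export
complex_pwm <- function(sites, cx, alpha = hth_config()$alpha) {
  reference <- paste(strand_bases(cx$duplex$forward), collapse = "")
  block <- align_sites(dedupe_sites(sites), reference)
  pwm <- build_pwm(block, alpha)
  list(pwm = pwm, map = map_pwm_to_structure(pwm, cx))
}

#' Sample binding sites from a PWM
#'
#' Draws `n` sequences column-independently; deterministic per seed.
#'
#' @param pwm a `pwm`.
#' @param n number of sites.
#' @param seed integer seed.
#' @return character vector of `n` sequences.
#' @export
sample_sites_from_pwm <- function(pwm, n, seed = 1L) {
  stopifnot(n >= 1L)
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state))
      assign(".Random.seed", rng_state, envir = globalenv())
  })
  set.seed(seed)
  L <- ncol(pwm)
  draws <- vapply(seq_len(L), function(j)
    sample(NUCLEOTIDES, n, replace = TRUE, prob = pwm[, j]), character(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1)
  apply(draws, 1, paste, collapse = "")
}
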