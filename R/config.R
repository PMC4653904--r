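#' Pipeline configuration with default cutoffs
#'
#' Collects every numeric cutoff used across the pipeline in one list.
#' Defaults:
#' \describe{
#'   \item{candidacy_cutoff}{5 Angstrom: the mean distance of the closest
#'     five contiguous recognition-helix residues to the DNA must be below
#'     this (strict) for a helix to be a candidate recognition helix.}
#'   \item{window}{5 residues: size of that contiguous window.}
#'   \item{orientation_cutoff}{6.5 Angstrom: each of the five window
#'     residues must individually lie within this distance of the DNA.}
#'   \item{trihelical_cutoff}{18 Angstrom: the central residue must have a
#'     C-alpha within this distance of at least one residue in each of two
#'     alpha-helices other than the recognition helix.}
#'   \item{delta}{2 Angstrom: DNA backbone RMSD gate for candidate
#'     alignments (strict).}
#'   \item{min_overlap}{8 residues: minimum recognition-helix overlap for
#'     the residue mapping search.}
#'   \item{max_shift}{15: largest recognition-sequence shift considered by
#'     the redundancy distance (keeps an 11-residue central window of both
#'     sequences inside the overlap).}
#'   \item{pair_c1_range}{c(9, 12) Angstrom: admissible C1'-C1' distance
#'     for geometric basepair matching.}
#'   \item{contact_cutoff}{5 Angstrom: default atomic contact threshold.}
#'   \item{alpha}{1: Laplace pseudocount for PWM construction.}
#'   \item{cognate_dna_cutoff}{10 Angstrom: a split domain must come within
#'     this distance of a DNA molecule to keep it as cognate.}
#'   \item{max_cluster_median}{3.5 Angstrom: bound on the main cluster's
#'     internal median RMSD accepted when tuning the clustering preference.}
#' }
#'
#' @param ... named overrides of any default.
#' @return A named list of class `hth_config`.
#' @export
hth_config <- function(...) {
  cfg <- list(
    candidacy_cutoff = 5,
    window = 5L,
    orientation_cutoff = 6.5,
    trihelical_cutoff = 18,
    delta = 2,
    min_overlap = 8L,
    max_shift = 15L,
    pair_c1_range = c(9, 12),
    contact_cutoff = 5,
    alpha = 1,
    cognate_dna_cutoff = 10,
    max_cluster_median = 3.5
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config option(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "hth_config")
}

#' Read a configuration file
#'
#' Structured-text (YAML) file of cutoff overrides; unspecified values keep
#' their defaults.
#'
#' @param path file path.
#' @return An `hth_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(hth_config, vals)
}

#' Write a configuration file
#' @param config an `hth_config`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
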