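# Synthetic HTH-DNA complex generator with known ground truth.
#
# Emulates the geometry the pipeline's distance heuristics probe: an
# idealized straight B-DNA duplex (backbone carbons on helical cylinders)
# plus a C-alpha-trace tri-helical bundle whose third (recognition) helix
# lies tangentially in the major groove. Each residue carries one CB
# pseudo side-chain atom; every distance definition in the pipeline uses
# only C-alpha, C1'-C5', or a minimum over atoms, so this reduced
# representation exercises all of them.

# B-DNA backbone atom placement: per-atom radius (A), angular offset
# (deg) relative to the glycosidic C1', and rise offset (A) along the
# helical axis, loosely following B-form backbone geometry.
BDNA_ATOM_GEOM <- data.frame(
  atom = BACKBONE_CARBONS,
  radius = c(9.4, 9.0, 9.2, 9.6, 9.9),
  dtheta = c(0, 12, 24, 20, 10),
  dz = c(0, 0.4, 1.0, 1.6, 2.2))

# Angular separation of the two C1' atoms of a basepair across the minor
# groove: with r = 9.4 A this puts the C1'-C1' distance at ~10.5 A.
BDNA_PAIR_ANGLE <- 68

#' Synthetic-complex parameters
#'
#' @param dna_length number of basepairs (>= 9 so that the five canonical
#'   matching regions fit around a centered anchor basepair).
#' @param dna_rise helical rise per basepair in Angstrom (B-form 3.4).
#' @param dna_twist helical twist per basepair in degrees (B-form 36).
#' @param helix_lengths residue counts of the three bundle helices, in
#'   N->C order; the last is the recognition helix.
#' @param dock_distance distance from the DNA helical axis to the
#'   recognition-helix axis in Angstrom. The default places the closest
#'   window residues 3-4.5 A from the DNA so all detection criteria pass.
#' @param bundle_offset radial offset of the two support helices behind
#'   the recognition helix (Angstrom).
#' @param bend_angle deflection, in degrees, of each duplex arm at a
#'   V-shaped kink through the dock basepair (0 = straight; the total
#'   bend of the duplex is twice this angle).
#' @param noise_sigma isotropic Gaussian jitter applied to every atom (A).
#' @param seed integer seed controlling the DNA sequence and any jitter.
#' @param dna_sequence optional explicit forward-strand sequence
#'   (overrides `dna_length`).
#' @param n_helices number of bundle helices actually emitted (3 default;
#'   2 builds a tri-helical-criterion decoy).
#' @param displaced_window_residue radial displacement (A) applied to the
#'   central recognition-helix residue, used to build orientation decoys.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(dna_length = 16L, dna_rise = 3.4, dna_twist = 36,
                         helix_lengths = c(10L, 9L, 13L),
                         dock_distance = 12, bundle_offset = 8,
                         bend_angle = 0, noise_sigma = 0, seed = 1L,
                         dna_sequence = NULL, n_helices = 3L,
                         displaced_window_residue = 0) {
  if (!is.null(dna_sequence)) dna_length <- nchar(dna_sequence)
  if (dna_length < 9L) stop("dna_length must be at least 9 basepairs")
  structure(list(dna_length = as.integer(dna_length), dna_rise = dna_rise,
                 dna_twist = dna_twist, helix_lengths = helix_lengths,
                 dock_distance = dock_distance,
                 bundle_offset = bundle_offset, bend_angle = bend_angle,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 dna_sequence = dna_sequence,
                 n_helices = as.integer(n_helices),
                 displaced_window_residue = displaced_window_residue),
            class = "synth_params")
}

#' Idealized straight B-DNA duplex
#'
#' Places the five backbone carbons of every nucleotide on helical
#' cylinders around the z axis (rise and twist per `params`), generates
#' the antiparallel complementary strand, and annotates basepairs.
#'
#' @param sequence forward-strand sequence over A/C/G/T.
#' @param params a `synth_params` (only rise/twist are used).
#' @return A `dna_duplex`.
#' @export
make_ideal_bdna <- function(sequence, params = synth_params()) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (!all(bases %in% names(BASE_COMPLEMENT)))
    stop("invalid base in sequence (A/C/G/T only)")
  L <- length(bases)
  place <- function(theta_deg, z0, antiparallel) {
    th <- (theta_deg + (if (antiparallel) -1 else 1) *
             BDNA_ATOM_GEOM$dtheta) * pi / 180
    data.frame(atom = BDNA_ATOM_GEOM$atom,
               element = "C",
               x = BDNA_ATOM_GEOM$radius * cos(th),
               y = BDNA_ATOM_GEOM$radius * sin(th),
               z = z0 + (if (antiparallel) -1 else 1) * BDNA_ATOM_GEOM$dz,
               stringsAsFactors = FALSE)
  }
  fwd <- do.call(rbind, lapply(seq_len(L), function(i) {
    at <- place((i - 1) * params$dna_twist, (i - 1) * params$dna_rise, FALSE)
    cbind(nt_index = i - 1L, base = bases[i], at)
  }))
  rev_ <- do.call(rbind, lapply(seq_len(L), function(j) {
    # reverse nucleotide j (0-based j-1, 5'->3' on its own strand) pairs
    # with forward nucleotide L-j (0-based L-j ... i.e. i0 = L - j)
    i0 <- L - j  # 0-based forward partner
    at <- place(i0 * params$dna_twist + BDNA_PAIR_ANGLE,
                i0 * params$dna_rise, TRUE)
    cbind(nt_index = j - 1L, base = unname(BASE_COMPLEMENT[bases[i0 + 1L]]),
          at)
  }))
  fwd <- fwd[, c("nt_index", "base", "atom", "element", "x", "y", "z")]
  rev_ <- rev_[, c("nt_index", "base", "atom", "element", "x", "y", "z")]
  dna_duplex(fwd, rev_, cbind(fwd = 0:(L - 1L), rev = (L - 1L):0))
}

# Ideal alpha-helix C-alpha/CB trace in a local frame: axis along +z,
# centered at the origin; 1.5 A rise, 100 deg twist, CA radius 2.3 A,
# CB radius 3.3 A.
ideal_helix_trace <- function(n) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  z <- (i - (n - 1) / 2) * 1.5
  list(ca = cbind(2.3 * cos(th), 2.3 * sin(th), z),
       cb = cbind(3.3 * cos(th), 3.3 * sin(th), z + 0.5))
}

# Ideal helix built in an explicit orthonormal frame (axis, u, v), with
# the phase anchored so that the middle residue's side of the helix
# points along +u. Residue index m = (n-1) %/% 2 sits exactly on +u,
# which makes it unambiguously the residue closest to whatever +u points
# at (its neighbours are 100 degrees away in phase).
helix_in_frame <- function(n, center, axis, u, v) {
  m <- (n - 1L) %/% 2L
  k <- seq_len(n) - 1L - m
  th <- k * 100 * pi / 180
  pos <- function(r, along, z_off = 0) {
    center_m <- matrix(center, n, 3, byrow = TRUE)
    center_m + outer(along * 1.5 + z_off, axis) +
      outer(r * cos(th), u) + outer(r * sin(th), v)
  }
  list(ca = pos(2.3, k), cb = pos(3.3, k, 0.5), mid = m)
}

# Rodrigues rotation matrix about a unit axis.
rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

helix_atoms_df <- function(res0, aas, placed) {
  n <- length(aas)
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(res_index = res0 + i - 1L, aa = aas[i],
               aa3 = unname(AA1_TO_3[aas[i]]),
               atom = c("CA", "CB"), element = "C",
               x = c(placed$ca[i, 1], placed$cb[i, 1]),
               y = c(placed$ca[i, 2], placed$cb[i, 2]),
               z = c(placed$ca[i, 3], placed$cb[i, 3]),
               stringsAsFactors = FALSE)))
}

#' Generate a synthetic HTH-DNA complex with ground truth
#'
#' Builds an idealized B-DNA duplex and docks a tri-helical C-alpha-trace
#' bundle so that, with default parameters, all three detection criteria
#' pass. The recognition helix lies tangentially in the major groove at
#' the duplex midpoint; the two support helices sit `bundle_offset`
#' further from the DNA axis. `bend_angle > 0` bends the DNA mid-helix
#' (atlas outlier mode); `n_helices = 2` and
#' `displaced_window_residue > 0` build single-criterion detection
#' decoys.
#'
#' @param params a `synth_params`.
#' @param structure_id,resolution metadata for the emitted complex.
#' @param check_detection verify that the emitted complex passes HTH
#'   detection, erroring on contradictory parameters (e.g. a dock
#'   distance too large to satisfy the candidacy criterion). Default:
#'   checked unless a decoy knob (`n_helices < 3`,
#'   `displaced_window_residue > 0`, `bend_angle > 0`) is set.
#' @return list with `complex` (an annotated `hth_complex`) and `truth`
#'   (recognition helix range, central residue, closest basepair `n`,
#'   helix segment table, applied transform).
#' @export
make_hth_complex <- function(params = synth_params(),
                             structure_id = "synth", resolution = 2.0,
                             check_detection = NULL) {
  stopifnot(inherits(params, "synth_params"))
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state))
      assign(".Random.seed", rng_state, envir = globalenv())
  })
  set.seed(params$seed)
  L <- params$dna_length
  seq_ <- if (!is.null(params$dna_sequence)) toupper(params$dna_sequence)
    else paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  duplex <- make_ideal_bdna(seq_, params)

  # dock the recognition helix tangentially at the middle basepair, its
  # axis midway (in angle) between the two backbone strands that flank
  # the groove at that height
  n_bp <- (L - 1L) %/% 2L
  alpha <- (n_bp * params$dna_twist + BDNA_PAIR_ANGLE / 4) * pi / 180
  radial <- c(cos(alpha), sin(alpha), 0)
  tangent <- c(-sin(alpha), cos(alpha), 0)
  z_dock <- n_bp * params$dna_rise
  nh <- params$helix_lengths
  if (params$n_helices < 3L) nh <- nh[seq_len(params$n_helices)]
  n_rec <- nh[length(nh)]
  aas_all <- sample(names(AA1_TO_3), sum(nh), replace = TRUE)
  protein <- NULL; res0 <- 0L; k0 <- 0L
  segs <- data.frame(start = integer(0), end = integer(0))
  zhat <- c(0, 0, 1)
  central_truth <- NA_integer_
  for (h in seq_along(nh)) {
    nres <- nh[h]
    if (h == length(nh)) {       # recognition helix, tangential in groove
      center <- params$dock_distance * radial + c(0, 0, z_dock)
    } else {                     # support helices, behind and offset in z
      center <- (params$dock_distance + params$bundle_offset) * radial +
        c(0, 0, z_dock + ifelse(h == 1, 6.5, -6.5))
    }
    # the middle residue's side points straight at the DNA axis, making
    # it the unambiguous central residue of the recognition helix
    placed <- helix_in_frame(nres, center, tangent, -radial, zhat)
    if (h == length(nh)) {
      central_truth <- res0 + placed$mid
      if (params$displaced_window_residue > 0) {
        mid <- placed$mid + 1L
        shift <- params$displaced_window_residue * radial
        placed$ca[mid, ] <- placed$ca[mid, ] + shift
        placed$cb[mid, ] <- placed$cb[mid, ] + shift
      }
    }
    protein <- rbind(protein,
                     helix_atoms_df(res0, aas_all[(k0 + 1):(k0 + nres)],
                                    placed))
    segs <- rbind(segs, data.frame(start = res0, end = res0 + nres))
    res0 <- res0 + nres; k0 <- k0 + nres
  }

  if (params$bend_angle > 0) {
    # V-shaped kink centered on the dock basepair: each arm deflects by
    # bend_angle (opposite senses) about the recognition-helix axis
    # direction through the hinge, swinging both arms away from the
    # protein. The kink basepair stays closest to the central residue,
    # so every canonical matching region straddles the kink and no clean
    # 5-bp window survives.
    half <- params$bend_angle * pi / 180
    hinge <- c(0, 0, z_dock)
    bend <- function(df, bp_of_nt) {
      arm <- sign(bp_of_nt - n_bp)   # per-nucleotide arm assignment
      for (a in c(-1, 1)) {
        sel <- arm[match(df$nt_index, sort(unique(df$nt_index)))] == a
        if (any(sel)) {
          xyz <- sweep(as.matrix(df[sel, c("x", "y", "z")]), 2, hinge)
          df[sel, c("x", "y", "z")] <-
            sweep(xyz %*% t(rotation_about(tangent, -a * half)), 2,
                  hinge, `+`)
        }
      }
      df
    }
    duplex$forward <- bend(duplex$forward, 0:(L - 1L))
    duplex$reverse <- bend(duplex$reverse, (L - 1L):0)
  }

  if (params$noise_sigma > 0) {
    jitter <- function(df) {
      df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(df), sd = params$noise_sigma),
               ncol = 3)
      df
    }
    protein <- jitter(protein)
    duplex$forward <- jitter(duplex$forward)
    duplex$reverse <- jitter(duplex$reverse)
  }

  rec <- c(segs$start[nrow(segs)], segs$end[nrow(segs)])
  cx <- hth_complex(structure_id, "A", protein, duplex,
                    resolution = resolution)
  cx$recognition_helix <- rec
  cx$central_residue <- central_truth
  n_truth <- closest_basepair(cx)
  if (is.null(check_detection))
    check_detection <- params$n_helices >= 3L &&
      params$displaced_window_residue <= 0 && params$bend_angle <= 0
  if (check_detection) {
    a <- detect_hth(cx)
    if (a$verdict != "pass")
      stop("contradictory parameters: generated complex fails HTH ",
           "detection at the ", a$failed_criterion, " criterion")
  }
  list(complex = cx,
       truth = list(recognition_helix = rec,
                    central_residue = central_truth,
                    closest_bp = n_truth, helices = segs,
                    dna_axis = list(point = c(0, 0, 0),
                                    direction = c(0, 0, 1)),
                    transform = rigid_transform()))
}

#' Rigidly perturb a complex
#'
#' Applies a proper rigid transform to every atom, then isotropic
#' Gaussian jitter; deterministic for a given seed.
#'
#' @param cx an `hth_complex`.
#' @param rotation 3x3 proper rotation (det +1).
#' @param translation length-3 numeric.
#' @param noise_sigma jitter standard deviation in Angstrom.
#' @param seed integer seed for the jitter.
#' @return list with `complex` and `truth` (the applied
#'   `rigid_transform`).
#' @export
perturb <- function(cx, rotation = diag(3), translation = c(0, 0, 0),
                    noise_sigma = 0, seed = 1L) {
  tr <- rigid_transform(rotation, translation)  # validates properness
  out <- transform_complex(cx, tr)
  if (noise_sigma > 0) {
    rng_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(rng_state))
        assign(".Random.seed", rng_state, envir = globalenv())
    })
    set.seed(seed)
    jitter <- function(df) {
      df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(df), sd = noise_sigma), ncol = 3)
      df
    }
    out$protein <- jitter(out$protein)
    out$duplex$forward <- jitter(out$duplex$forward)
    out$duplex$reverse <- jitter(out$duplex$reverse)
  }
  list(complex = out, truth = list(transform = tr))
}
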