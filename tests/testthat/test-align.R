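test_that("closest basepair matches generator truth and brute force", {
  g <- fixture_complex(seed = 5)
  cx <- g$complex
  n <- closest_basepair(cx)
  expect_equal(n, g$truth$closest_bp)
  ca <- protein_ca(cx)[as.character(cx$central_residue), ]
  d <- vapply(0:(n_basepairs(cx) - 1L), function(b)
    min(sqrt(rowSums(sweep(hthatlas:::bp_c1_coords(cx, b), 2, ca)^2))),
    numeric(1))
  expect_equal(n, which.min(d) - 1L)
  # invariant under rigid motion
  moved <- transform_complex(cx, rigid_transform(random_rotation(seed = 2),
                                                 c(7, 8, 9)))
  expect_equal(closest_basepair(moved), n)
})

test_that("five canonical regions, each containing the anchor basepair", {
  cx <- fixture_complex(seed = 5)$complex
  regs <- canonical_matching_regions(cx)
  n <- attr(regs, "anchor_bp")
  expect_length(regs, 5L)
  starts <- vapply(regs, function(r) r$start, integer(1))
  expect_equal(starts, (n - 4L):n)
  for (r in regs) {
    expect_equal(r$span, 5L)
    expect_true(n >= r$start && n <= r$start + 4L)
    expect_equal(dim(r$fwd), c(25L, 3L))
  }
  # anchor too close to the duplex end -> error naming the side
  expect_error({
    cx2 <- cx
    dx <- cx2$duplex
    keep <- 5:15  # drop the five 5'-most basepairs
    f <- dx$forward[dx$forward$nt_index %in% keep, ]
    f$nt_index <- f$nt_index - 5L
    r <- dx$reverse[dx$reverse$nt_index %in% (15 - keep), ]
    r$nt_index <- r$nt_index - 0L
    cx2$duplex <- dna_duplex(f, r, cbind(fwd = 0:10, rev = 10:0))
    canonical_matching_regions(cx2)
  }, "5'")
})

test_that("region correspondence preserves atom type and is an involution", {
  cx <- fixture_complex(seed = 5)$complex
  regs <- canonical_matching_regions(cx)
  ra <- regs[[1]]; rb <- regs[[3]]
  fwd <- region_correspondence(ra, rb, "FORWARD")
  expect_equal(nrow(fwd$a), 50L)
  expect_true(all(fwd$pairs$a_atom == fwd$pairs$b_atom))
  # forward self-correspondence is the identity pairing
  self <- region_correspondence(ra, ra, "FORWARD")
  expect_identical(self$a, self$b)
  # flipped: basepair order reversed, strands swapped, atom types kept
  flp <- region_correspondence(ra, rb, "FLIPPED")
  expect_true(all(flp$pairs$a_atom == flp$pairs$b_atom))
  expect_true(all(flp$pairs$b_bp == 4L - flp$pairs$a_bp))
  expect_true(all(flp$pairs$a_strand != flp$pairs$b_strand))
  # flipping twice recovers the forward pairing
  refl <- flp$pairs
  again <- data.frame(bp = 4L - refl$b_bp,
                      strand = ifelse(refl$b_strand == "F", "R", "F"))
  expect_equal(again$bp, refl$a_bp)
  expect_equal(again$strand, refl$a_strand)
})

test_that("superposition recovers exact transforms and noise brackets", {
  cx <- fixture_complex(seed = 5)$complex
  reg <- canonical_matching_regions(cx)[[2]]
  pts <- rbind(reg$fwd, reg$rev)
  # pure translation
  sp <- superpose(pts + matrix(c(3, -4, 5), 50, 3, byrow = TRUE), pts)
  expect_lt(sp$rmsd, 1e-9)
  expect_lt(max(abs(sp$transform$R - diag(3))), 1e-9)
  expect_equal(sp$transform$t, c(-3, 4, -5), tolerance = 1e-9)
  # known rotation
  R <- random_rotation(seed = 31)
  sp2 <- superpose(pts %*% t(R), pts)
  expect_lt(sp2$rmsd, 1e-9)
  expect_lt(max(abs(sp2$transform$R - t(R))), 1e-6)
  # Gaussian noise sigma = 0.3 A: rmsd within the Monte-Carlo bracket
  set.seed(99)
  rms <- replicate(100, {
    noisy <- pts + matrix(stats::rnorm(150, sd = 0.3), 50, 3)
    superpose(noisy, pts)$rmsd
  })
  expect_true(all(rms > 0.15 & rms < 0.6))
  # degenerate collinear input errors
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(superpose(line, line), "degenerate")
})

test_that("candidate enumeration is complete, ordered, and gated strictly", {
  a <- fixture_complex(seed = 5)$complex
  b <- fixture_complex(seed = 6)$complex
  cands <- enumerate_candidates(a, b)
  expect_length(cands, 50L)
  expect_equal(length(unique(vapply(cands, function(c)
    paste(c$region_a, c$region_b), character(1)))), 25L)
  ord <- vapply(cands, function(c)
    c$region_a * 10 + c$region_b * 2 + (c$orientation == "FLIPPED"),
    numeric(1))
  expect_equal(ord, sort(ord))
  expect_length(gate_candidates(cands, Inf), 50L)
  # the gate is strict: rmsd exactly at delta is eliminated
  fake <- list(list(dna_rmsd = 2.0), list(dna_rmsd = 1.999))
  expect_length(gate_candidates(fake, 2.0), 1L)
  # identical complexes: all forward self-pairings survive at rmsd ~ 0
  self <- gate_candidates(enumerate_candidates(a, a), 2)
  diag_fwd <- Filter(function(c) c$region_a == c$region_b &&
                       c$orientation == "FORWARD", self)
  expect_length(diag_fwd, 5L)
  expect_true(all(vapply(diag_fwd, function(c) c$dna_rmsd, numeric(1)) <
                    1e-9))
})

test_that("helix mapping minimizes RMSD over shifts and flips (oracle)", {
  set.seed(55)
  for (k in 1:25) {
    la <- sample(10:18, 1); lb <- sample(10:18, 1)
    ha <- matrix(stats::rnorm(3 * la, sd = 4), la, 3)
    hb <- matrix(stats::rnorm(3 * lb, sd = 4), lb, 3)
    rownames(ha) <- 0:(la - 1); rownames(hb) <- 0:(lb - 1)
    got <- helix_rmsd_under_mapping(ha, hb, rigid_transform())
    expect_equal(got$rmsd, oracle_helix_rmsd(ha, hb), tolerance = 1e-9)
    expect_gte(nrow(got$residue_map), 8L)
  }
  # identical helices under the identity transform: zero at zero shift
  ha <- matrix(stats::rnorm(36), 12, 3); rownames(ha) <- 0:11
  got <- helix_rmsd_under_mapping(ha, ha, rigid_transform())
  expect_equal(got$rmsd, 0)
  expect_equal(got$shift, 0L)
  expect_false(got$flipped)
  # two 8-residue helices admit exactly the two zero-shift mappings
  h8 <- hthatlas:::ideal_helix_trace(8)$ca; rownames(h8) <- 0:7
  got8 <- helix_rmsd_under_mapping(h8, h8, rigid_transform())
  expect_equal(got8$shift, 0L)
  flipped_rmsd <- oracle_helix_rmsd(h8, h8[8:1, , drop = FALSE])
  expect_equal(min(got8$rmsd, flipped_rmsd), got8$rmsd)
  expect_error(helix_rmsd_under_mapping(h8[1:6, ], h8, rigid_transform()),
               "shorter")
})

test_that("align_pair recovers rigid motions exactly", {
  cx <- fixture_complex(seed = 5)$complex
  tr <- rigid_transform(random_rotation(seed = 77), c(10, -4, 6))
  moved <- perturb(cx, tr$R, tr$t)$complex
  al <- align_pair(cx, moved)
  expect_s3_class(al, "pairwise_alignment")
  expect_lt(al$dna_rmsd, 1e-6)
  expect_lt(al$helix_rmsd, 1e-6)
  inv <- invert_transform(tr)
  expect_lt(max(abs(al$transform$R - inv$R)), 1e-6)
  expect_lt(max(abs(al$transform$t - inv$t)), 1e-6)
  # identity alignment of a complex to itself
  al0 <- align_pair(cx, cx)
  expect_lt(al0$helix_rmsd, 1e-6)
  expect_equal(al0$residue_map[, "a"], al0$residue_map[, "b"])
  expect_equal(al0$basepair_map[, "a"], al0$basepair_map[, "b"])
})

test_that("strand relabeling is resolved by the FLIPPED orientation", {
  cx <- fixture_complex(seed = 5)$complex
  al <- align_pair(cx, flip_duplex(cx))
  expect_equal(al$orientation, "FLIPPED")
  expect_lt(al$helix_rmsd, 1e-6)
  L <- n_basepairs(cx)
  # basepair b of the relabeled copy is basepair L-1-b of the original
  expect_equal(al$basepair_map[, "b"], L - 1L - al$basepair_map[, "a"])
})

test_that("alignment RMSDs are symmetric and rigid-motion invariant", {
  a <- fixture_complex(seed = 5)$complex
  b <- fixture_complex(seed = 6)$complex
  ab <- align_pair(a, b); ba <- align_pair(b, a)
  expect_equal(ab$helix_rmsd, ba$helix_rmsd, tolerance = 1e-6)
  expect_equal(ab$dna_rmsd, ba$dna_rmsd, tolerance = 1e-6)
  comp <- compose_transforms(ab$transform, ba$transform)
  expect_lt(max(abs(comp$R - diag(3))), 1e-6)
  expect_lt(max(abs(comp$t)), 1e-6)
  for (k in 1:10) {
    moved <- transform_complex(
      b, rigid_transform(random_rotation(seed = 300 + k),
                         stats::rnorm(3, sd = 15)))
    al <- align_pair(a, moved)
    expect_equal(al$helix_rmsd, ab$helix_rmsd, tolerance = 1e-6)
    expect_equal(al$dna_rmsd, ab$dna_rmsd, tolerance = 1e-6)
  }
})

test_that("expected DNA RMSD grows with coordinate noise", {
  cx <- fixture_complex(seed = 5)$complex
  mean_rmsd <- vapply(c(0.05, 0.15, 0.45), function(sig) {
    mean(vapply(1:15, function(k) {
      noisy <- perturb(cx, diag(3), c(0, 0, 0), noise_sigma = sig,
                       seed = 1000 + k)$complex
      align_pair(cx, noisy)$dna_rmsd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rmsd) > 0))
})

test_that("geometry-identical complexes align at zero despite sequences", {
  p1 <- synth_params(seed = 21, dna_sequence = paste(
    rep("A", 16), collapse = ""))
  p2 <- synth_params(seed = 21, dna_sequence = paste(
    rep("G", 16), collapse = ""))
  c1 <- make_hth_complex(p1)$complex
  c2 <- make_hth_complex(p2)$complex
  al <- align_pair(c1, c2)
  expect_lt(al$helix_rmsd, 1e-6)
})
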