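test_that("structures round-trip through PDB text", {
  cx <- fixture_complex(seed = 2)$complex
  txt <- write_structure(cx)
  cx2 <- read_complex(txt, structure_id = cx$structure_id)
  expect_lt(max(abs(protein_ca(cx) - protein_ca(cx2))), 1e-3)
  expect_equal(n_basepairs(cx2), n_basepairs(cx))
  expect_equal(strand_bases(cx2$duplex$forward),
               strand_bases(cx$duplex$forward))
  # write -> read -> write is a fixpoint (byte-identical)
  txt2 <- write_structure(hth_complex(cx$structure_id, "A", cx2$protein,
                                      cx2$duplex))
  expect_identical(txt2, txt)
})

test_that("a transformed complex writes transformed coordinates", {
  cx <- fixture_complex(seed = 2)$complex
  tr <- rigid_transform(random_rotation(seed = 5), c(1, -2, 3))
  moved <- transform_complex(cx, tr)
  back <- read_complex(write_structure(moved))
  expect_lt(max(abs(protein_ca(back) -
                      transform_coords(tr, protein_ca(cx)))), 1e-3)
})

test_that("writing refuses an empty protein", {
  cx <- fixture_complex(seed = 2)$complex
  cx$protein <- cx$protein[0, ]
  expect_error(write_structure(cx), "empty protein")
})

test_that("a minimal one-residue PDB parses to one protein residue", {
  line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  raw <- read_structure(c(line, "END"))
  expect_length(raw$protein, 1L)
  p <- raw$protein[[1]]
  expect_equal(nrow(p), 1L)
  expect_equal(p$aa, "A")
  expect_equal(c(p$x, p$y, p$z), c(1, 2, 3))
})

test_that("only the first alternate location of an atom is kept", {
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   2.000   3.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  0.50  0.00           C",
    "END")
  raw <- read_structure(lines)
  p <- raw$protein[[1]]
  expect_equal(nrow(p), 1L)
  expect_equal(p$x, 1)
})

test_that("pathology screening flags each pathology class", {
  cx <- fixture_complex(seed = 4)$complex
  raw <- read_structure(write_structure(cx))
  expect_true(is_admissible(screen_pathologies(raw)))

  # drop one C3' -> missing backbone atoms
  raw2 <- raw
  d <- raw2$dna[[1]]
  drop <- which(d$nt_index == 3 & d$atom == "C3'")
  raw2$dna[[1]] <- d[-drop, ]
  expect_identical(screen_pathologies(raw2)$flags, "MISSING_BACKBONE_ATOMS")

  # selenomethionine -> non-standard residue
  raw3 <- raw
  raw3$protein[[1]]$aa3[raw3$protein[[1]]$res_index == 0] <- "MSE"
  expect_identical(screen_pathologies(raw3)$flags, "NONSTANDARD_RESIDUES")

  # single strand -> single-stranded DNA
  raw4 <- raw
  raw4$dna <- raw4$dna[1]
  expect_identical(screen_pathologies(raw4)$flags, "SINGLE_STRANDED_DNA")

  # protein residue without CA
  raw5 <- raw
  p <- raw5$protein[[1]]
  raw5$protein[[1]] <- p[!(p$res_index == 0 & p$atom == "CA"), ]
  expect_true("MISSING_BACKBONE_ATOMS" %in% screen_pathologies(raw5)$flags)
})

test_that("duplex standardization removes overhangs and is idempotent", {
  cx <- fixture_complex(seed = 6)$complex
  dx <- cx$duplex
  # graft a 2-nt 5' overhang onto the forward strand
  ext <- make_ideal_bdna("AC", synth_params())$forward
  ext$x <- ext$x + 100  # far from everything: cannot pair
  ext$nt_index <- ext$nt_index - 2L
  long <- rbind(ext, dx$forward)
  long$nt_index <- long$nt_index + 2L
  std <- standardize_duplex(list(F = long, R = dx$reverse))
  expect_equal(n_basepairs(std), n_basepairs(cx))
  expect_equal(strand_bases(std$forward), strand_bases(dx$forward))
  # coordinates are never altered, only records removed/reordered
  expect_equal(sort(std$forward$x), sort(dx$forward$x))
  # idempotence
  std2 <- standardize_duplex(list(F = std$forward, R = std$reverse))
  expect_identical(std2$pairs, std$pairs)
  expect_equal(std2$forward, std$forward, ignore_attr = TRUE)
})

test_that("a strand listed 3'->5' is reordered with coordinates untouched", {
  cx <- fixture_complex(seed = 6)$complex
  dx <- cx$duplex
  rev_wrong <- dx$reverse
  rev_wrong$nt_index <- max(rev_wrong$nt_index) - rev_wrong$nt_index
  std <- standardize_duplex(list(F = dx$forward, R = rev_wrong))
  expect_equal(strand_bases(std$reverse), strand_bases(dx$reverse))
  ord <- function(s) s[order(s$nt_index, s$atom), c("x", "y", "z")]
  expect_equal(ord(std$reverse), ord(dx$reverse), ignore_attr = TRUE)
})

test_that("standardization rejects unpairable inputs", {
  cx <- fixture_complex(seed = 6)$complex
  expect_error(standardize_duplex(list(F = cx$duplex$forward)),
               "SINGLE_STRANDED_DNA")
  far <- cx$duplex$reverse
  far$x <- far$x + 500
  expect_error(standardize_duplex(list(F = cx$duplex$forward, R = far)),
               "no consistent basepairing")
})

test_that("split_domains cuts a two-domain chain into two complexes", {
  g1 <- fixture_complex(seed = 7)
  base <- g1$complex
  # build a two-domain chain: the same bundle twice, second copy shifted
  # along the DNA axis and renumbered
  p2 <- base$protein
  p2$z <- p2$z + 6.8  # two basepairs further along
  p2$res_index <- p2$res_index + max(base$protein$res_index) + 1L
  raw <- structure(list(
    protein = list(A = rbind(base$protein, p2)),
    dna = list(B = base$duplex$forward, C = base$duplex$reverse),
    helix = NULL), class = "hth_raw")
  nres <- max(base$protein$res_index) + 1L
  doms <- list(
    list(segments = data.frame(chain = "A", start = 0L, end = nres),
         structure_id = "dom1"),
    list(segments = data.frame(chain = "A", start = nres,
                               end = 2L * nres),
         structure_id = "dom2"))
  out <- split_domains(raw, doms)
  expect_length(out, 2L)
  expect_equal(sort(unique(out[[2]]$protein$res_index)), 0:(nres - 1L))
  expect_equal(out[[1]]$structure_id, "dom1")
  # a domain far from the DNA is excluded with a reason
  p3 <- base$protein
  p3$x <- p3$x + 300
  p3$res_index <- p3$res_index + nres
  raw$protein$A <- rbind(base$protein, p3)
  out2 <- split_domains(raw, doms)
  expect_length(out2, 1L)
  expect_match(attr(out2, "excluded")$dom2, "no cognate DNA")
})

test_that("single-domain split reproduces the input complex", {
  base <- fixture_complex(seed = 7)$complex
  raw <- structure(list(
    protein = list(A = base$protein),
    dna = list(B = base$duplex$forward, C = base$duplex$reverse),
    helix = NULL), class = "hth_raw")
  nres <- max(base$protein$res_index) + 1L
  out <- split_domains(raw, list(list(
    segments = data.frame(chain = "A", start = 0L, end = nres),
    structure_id = "whole")))
  expect_length(out, 1L)
  expect_equal(out[[1]]$protein$x, base$protein$x)
  expect_equal(n_basepairs(out[[1]]), n_basepairs(base))
})

test_that("duplex validation enforces complementarity and pairing shape", {
  dx <- make_ideal_bdna("ACGTACGTAC", synth_params())
  bad <- dx$forward
  bad$base[bad$nt_index == 0] <- "G"  # breaks Watson-Crick pairing
  expect_error(dna_duplex(bad, dx$reverse, dx$pairs), "complementary")
  expect_error(dna_duplex(dx$forward, dx$reverse,
                          dx$pairs[nrow(dx$pairs):1, ]), "bijection")
})
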