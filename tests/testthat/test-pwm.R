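make_sites_df <- function(seqs, prov = NA_character_) {
  data.frame(complex_id = "cx", sequence = seqs, source = "test",
             experiment_type = "synthetic", quality = "",
             provenance_id = rep_len(prov, length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("site deduplication keeps unique experiments", {
  # same provenance + same sequence collapses to one
  s <- make_sites_df(c("ACGT", "ACGT"), prov = "PMID:1")
  expect_equal(nrow(dedupe_sites(s)), 1L)
  # same sequence from distinct experiments is retained
  s2 <- make_sites_df(c("ACGT", "ACGT"))
  s2$provenance_id <- c("PMID:1", "PMID:2")
  expect_equal(nrow(dedupe_sites(s2)), 2L)
  # records without provenance are always kept
  s3 <- make_sites_df(c("ACGT", "ACGT"), prov = NA)
  expect_equal(nrow(dedupe_sites(s3)), 2L)
  expect_equal(nrow(dedupe_sites(s3[0, ])), 0L)
})

test_that("sites align to the reference at the best offset and strand", {
  ref <- "ACGTTGCAAC"
  # exact substring -> placed forward at its offset
  b1 <- align_sites("GTTGC", ref)
  expect_equal(attr(b1, "offset"), 2L)
  expect_equal(attr(b1, "strand"), "forward")
  expect_equal(b1[1, 3:7], strsplit("GTTGC", "")[[1]])
  expect_true(all(is.na(b1[1, c(1, 2, 8, 9, 10)])))
  # reverse-complement of a (non-palindromic) substring -> placed reverse
  b2 <- align_sites(hthatlas:::reverse_complement("CGTTG"), ref)
  expect_equal(attr(b2, "strand"), "reverse")
  expect_equal(b2[1, 2:6], strsplit("CGTTG", "")[[1]])
  # over-long site trimmed with warning
  expect_warning(align_sites(paste0(ref, "AC"), ref), "trimmed")
})

test_that("site placement matches exhaustive offset x strand search", {
  set.seed(77)
  for (k in 1:30) {
    ref <- paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = "")
    site <- paste(sample(c("A", "C", "G", "T"), sample(5:10, 1), TRUE),
                  collapse = "")
    got <- align_sites(site, ref)
    refv <- strsplit(ref, "")[[1]]
    best <- -1L
    for (str in c("forward", "reverse")) {
      sv <- strsplit(if (str == "forward") site else
        hthatlas:::reverse_complement(site), "")[[1]]
      for (off in 0:(14 - length(sv)))
        best <- max(best, sum(sv == refv[(off + 1):(off + length(sv))]))
    }
    sv_placed <- got[1, !is.na(got[1, ])]
    off <- attr(got, "offset")
    expect_equal(sum(sv_placed == refv[(off + 1):(off + length(sv_placed))]),
                 best)
  }
})

test_that("Laplace smoothing follows the add-alpha formula", {
  block <- matrix(c("A", "A", "A", "A",
                    NA, NA, NA, NA,
                    "A", "C", "G", "T"), nrow = 4)
  pwm <- build_pwm(block, alpha = 1)
  expect_equal(pwm[, 1], c(A = 5 / 8, C = 1 / 8, G = 1 / 8, T = 1 / 8))
  expect_equal(pwm[, 2], c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(unname(colSums(pwm)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(pwm > 0))
  expect_equal(attr(pwm, "support"), c(4L, 0L, 4L))
  # in the large-sample limit columns converge to the frequencies
  set.seed(5)
  big <- matrix(sample(c("A", "C", "G", "T"), 1e4, TRUE,
                       prob = c(.5, .3, .15, .05)), ncol = 1)
  pbig <- build_pwm(big, alpha = 1)
  expect_equal(unname(pbig[, 1]), c(.5, .3, .15, .05), tolerance = 0.02)
})

test_that("structure mapping places columns on basepairs both ways", {
  cx <- fixture_complex(seed = 2)$complex
  L <- n_basepairs(cx)
  ref <- paste(strand_bases(cx$duplex$forward), collapse = "")
  block <- align_sites(substr(ref, 1, L), ref)
  pwm <- build_pwm(block)
  m <- map_pwm_to_structure(pwm, cx)
  expect_equal(m$map[, "column"], m$map[, "bp"])
  expect_equal(dim(m$bp_distributions), c(4L, L))
  # short pwm at an offset: flanking basepairs carry the uniform prior
  pwm5 <- build_pwm(align_sites("ACGTA", "ACGTA"))
  m5 <- map_pwm_to_structure(pwm5, cx, offset = 3L)
  expect_equal(m5$map[, "bp"], 3:7)
  expect_equal(unname(m5$bp_distributions[, 1]), rep(.25, 4))
  expect_equal(unname(m5$bp_distributions[, 4]), unname(pwm5[, 1]))
  # reverse orientation: order reversed, columns complement-swapped
  mr <- map_pwm_to_structure(pwm5, cx, offset = 3L,
                             orientation = "reverse")
  expect_equal(mr$map[, "bp"], rev(3:7))
  # basepair 3 carries the complement of the last column
  expect_equal(unname(mr$bp_distributions[c("A", "C", "G", "T"), 4]),
               unname(pwm5[c("T", "G", "C", "A"), 5]))
})

test_that("reverse-complement consistency of PWM construction is exact", {
  set.seed(31)
  ref <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
  sites <- vapply(1:8, function(k) {
    off <- sample(0:6, 1)
    substr(ref, off + 1, off + 6)
  }, character(1))
  p_fwd <- build_pwm(align_sites(sites, ref))
  p_rc <- build_pwm(align_sites(hthatlas:::reverse_complement(sites),
                                hthatlas:::reverse_complement(ref)))
  flipped <- p_rc[c("T", "G", "C", "A"), ncol(p_rc):1]
  dimnames(flipped) <- dimnames(p_fwd)
  expect_equal(unclass(p_fwd), unclass(flipped), ignore_attr = TRUE)
})

test_that("sampling from a PWM is deterministic and recoverable", {
  set.seed(13)
  raw <- matrix(stats::rexp(4 * 9), 4, 9,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- structure(sweep(raw, 2, colSums(raw), `/`),
                   class = c("pwm", "matrix", "array"))
  expect_identical(sample_sites_from_pwm(pwm, 20, seed = 9),
                   sample_sites_from_pwm(pwm, 20, seed = 9))
  # a delta-function pwm emits only the consensus
  delta <- structure(matrix(rep(c(1, 0, 0, 0), 5), 4, 5,
                            dimnames = list(c("A", "C", "G", "T"), NULL)),
                     class = c("pwm", "matrix", "array"))
  expect_true(all(sample_sites_from_pwm(delta, 10, seed = 1) == "AAAAA"))
  # recovery: total variation shrinks as the sample grows
  tv <- function(n, seed) {
    sites <- sample_sites_from_pwm(pwm, n, seed = seed)
    block <- do.call(rbind, strsplit(sites, ""))
    est <- build_pwm(block, alpha = 1)
    max(colSums(abs(est - pwm)) / 2)
  }
  tv_small <- vapply(1:10, function(s) tv(100, s), numeric(1))
  tv_big <- vapply(1:10, function(s) tv(1e4, s), numeric(1))
  expect_lt(mean(tv_big), mean(tv_small) / 2)
  expect_lt(mean(tv_big), 0.02)
})

test_that("PWM files and site tables round-trip through disk", {
  set.seed(17)
  raw <- matrix(stats::rexp(4 * 6), 4, 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- structure(sweep(raw, 2, colSums(raw), `/`),
                   class = c("pwm", "matrix", "array"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(unclass(back), unclass(pwm), tolerance = 1e-12,
               ignore_attr = TRUE)
  sf <- withr::local_tempfile(fileext = ".tsv")
  df <- make_sites_df(c("ACGT", "GGTA"), prov = c("p1", "p2"))
  utils::write.table(df, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_sites(sf)
  expect_equal(got$sequence, df$sequence)
  bad <- df; bad$sequence[1] <- "ACGN"
  utils::write.table(bad, sf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_sites(sf), "invalid")
})
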