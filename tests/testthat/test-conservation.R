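test_that("pairs map through reference gaps to the right alignment columns", {
  aln <- alignment_block(c(mouse = "ACGUACGUAC", human = "ACGUACGUAC"))
  st <- secondary_structure(10, data.frame(i = 2, j = 9))
  cp <- map_pairs(st, aln)
  expect_equal(c(cp$col_i, cp$col_j), c(2L, 9L))   # ungapped: identity

  # one gap inserted at column 3 shifts reference positions 3+ right by one
  aln2 <- alignment_block(c(mouse = "AC-GUACGUAC", human = "ACUGUACGUAC"))
  st2 <- secondary_structure(10, data.frame(i = 3, j = 8))
  cp2 <- map_pairs(st2, aln2)
  expect_equal(c(cp2$col_i, cp2$col_j), c(4L, 9L))

  st_far <- secondary_structure(30, data.frame(i = 3, j = 25))
  expect_error(map_pairs(st_far, aln), "beyond the reference")
})

test_that("pair conservation counts canonical pairs including GU wobble", {
  # three identical sequences, two GC pairs: fully conserved
  rows <- c(m = "GGAAAACC", s1 = "GGAAAACC", s2 = "GGAAAACC")
  aln <- alignment_block(rows)
  st <- secondary_structure(8, data.frame(i = c(1, 2), j = c(8, 7)))
  rep1 <- score_pair_conservation(aln, map_pairs(st, aln))
  expect_equal(rep1$canonical_fraction, c(1, 1))
  expect_equal(attr(rep1, "conservation_pct"), 100)

  # one of four species breaks one of two pairs (GC -> GA)
  rows2 <- c(m = "GGAAAACC", s1 = "GGAAAACC", s2 = "GGAAAACC",
             s3 = "GGAAAAAC")                       # pair (2,7): G:A
  aln2 <- alignment_block(rows2)
  rep2 <- score_pair_conservation(aln2, map_pairs(st, aln2))
  expect_equal(rep2$canonical_fraction, c(1, 0.75))
  expect_equal(attr(rep2, "conservation_pct"), 87.5)

  # GC -> GU stays canonical
  rows3 <- c(m = "GGAAAACC", s1 = "GGAAAAUC")
  aln3 <- alignment_block(rows3)
  rep3 <- score_pair_conservation(aln3, map_pairs(st, aln3))
  expect_equal(rep3$canonical_fraction, c(1, 1))

  # a gap counts against conservation
  rows4 <- c(m = "GGAAAACC", s1 = "GGAAAA-C")
  aln4 <- alignment_block(rows4)
  rep4 <- score_pair_conservation(aln4, map_pairs(st, aln4))
  expect_equal(rep4$canonical_fraction, c(1, 0.5))
})

test_that("consistent and compensatory mutations are disjoint and well defined", {
  st <- secondary_structure(8, data.frame(i = 2, j = 7))
  # reference pair G:C
  ident <- alignment_block(c(m = "AGAAAACA", s1 = "AGAAAACA"))
  m0 <- classify_mutations(ident, map_pairs(st, ident))
  expect_equal(attr(m0, "n_pairs_consistent"), 0L)
  expect_equal(attr(m0, "n_pairs_compensatory"), 0L)

  # G:C -> A:U, both changed, still canonical: compensatory
  comp <- alignment_block(c(m = "AGAAAACA", s1 = "AAAAAAUA"))
  m1 <- classify_mutations(comp, map_pairs(st, comp))
  expect_equal(m1$n_compensatory_species, 1L)
  expect_equal(m1$n_consistent_species, 0L)

  # G:C -> G:U, one changed, canonical: consistent
  cons <- alignment_block(c(m = "AGAAAACA", s1 = "AGAAAAUA"))
  m2 <- classify_mutations(cons, map_pairs(st, cons))
  expect_equal(m2$n_consistent_species, 1L)
  expect_equal(m2$n_compensatory_species, 0L)

  # reference U:A, species C:A: one changed but non-canonical -> neither
  stU <- secondary_structure(8, data.frame(i = 2, j = 7))
  ua <- alignment_block(c(m = "AUAAAAAA", s1 = "ACAAAAAA"))
  m3 <- classify_mutations(ua, map_pairs(stU, ua))
  expect_equal(m3$n_consistent_species + m3$n_compensatory_species, 0L)
})

test_that("an alignment of reference copies is 100% conserved for any structure", {
  set.seed(21)
  bases <- sample(c("A", "C", "G", "U"), 60, replace = TRUE)
  seq <- paste(bases, collapse = "")
  st <- mfe_fold(seq, engine = engine_builtin())
  expect_gt(nrow(st$pairs), 0L)
  aln <- alignment_block(stats::setNames(rep(seq, 5), paste0("sp", 1:5)))
  rep <- conservation_report(st, aln)
  expect_equal(attr(rep, "summary")$conservation_pct, 100)
  expect_equal(attr(rep, "summary")$consistent, 0L)
  expect_equal(attr(rep, "summary")$compensatory, 0L)
  expect_equal(attr(rep, "summary")$bps, nrow(st$pairs))
})

test_that("random alignment rows drive conservation toward the background rate", {
  set.seed(33)
  n <- 80
  bases <- c(rbind(sample(c("G", "C"), n / 2, replace = TRUE),
                   sample(c("A", "U"), n / 2, replace = TRUE)))
  seq <- paste(bases, collapse = "")
  st <- mfe_fold(seq, engine = engine_builtin())
  n_random <- 300
  rows <- c(ref = seq,
            stats::setNames(vapply(seq_len(n_random), function(k)
              paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                    collapse = ""), character(1)), paste0("r", seq_len(n_random))))
  aln <- alignment_block(rows, reference = "ref")
  rep <- score_pair_conservation(aln, map_pairs(st, aln))
  # uniform random residues pair canonically with probability 6/16
  expected <- (1 + n_random * 6 / 16) / (n_random + 1)
  expect_equal(mean(rep$canonical_fraction), expected, tolerance = 0.05)
})

test_that("alignment files load through Biostrings and subsetting keeps the reference", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">mouse", "GGAAAACC", ">rat", "GGAAAACC", ">human", "GGAAAAUC"), fa)
  aln <- read_alignment(fa, reference = "mouse")
  expect_equal(rownames(aln$seqs), c("mouse", "rat", "human"))
  rodents <- subset_alignment(aln, c("rat"))
  expect_equal(sort(rownames(rodents$seqs)), c("mouse", "rat"))
  expect_error(subset_alignment(aln, "yeast"), "not in alignment")
})
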