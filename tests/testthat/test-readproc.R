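test_that("leading random-mer clipping removes exactly 3 nt and skips short reads", {
  out <- clip_reads(c("NNNACGT", "NNNA"), c("IIIIIII", "IIII"))
  expect_equal(out$reads, c("ACGT", "A"))
  expect_equal(out$qualities, c("IIII", "I"))
  expect_equal(out$n_skipped, 0L)

  short <- clip_reads(c("NNN", "NNNACGT"))
  expect_equal(short$reads, "ACGT")
  expect_equal(short$n_skipped, 1L)

  empty <- clip_reads(character(0))
  expect_equal(empty$reads, character(0))
  expect_equal(empty$n_skipped, 0L)
})

test_that("FASTQ clipping preserves order and clips qualities in lockstep", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "NNNACGTACGT", "+", "IIIHHHGGGFF",
               "@r2", "NNT", "+", "III",
               "@r3", "NNNGGGG", "+", "IIIJJJJ"), fq)
  out <- tempfile(fileext = ".fastq")
  expect_message(n <- clip_fastq(fq, out), "skipped")
  expect_equal(n, 1L)
  lines <- readLines(out)
  expect_equal(lines[2], "ACGTACGT")
  expect_equal(lines[4], "HHHGGGFF")
  expect_equal(sub("^@", "", lines[c(1, 5)]), c("r1", "r3"))
  expect_equal(lines[6], "GGGG")
})

test_that("alignment filters keep >= 60 nt and <= 2 mismatches, boundaries included", {
  reads <- make_reads(start = c(1, 1, 1, 1), end = c(59, 60, 75, 70),
                      mismatches = c(0L, 2L, 3L, NA))
  out <- filter_alignments(reads)
  expect_equal(out$end, 60)
  expect_equal(attr(out, "n_short"), 1L)
  expect_equal(attr(out, "n_mismatch"), 1L)
  expect_equal(attr(out, "n_missing_mismatch"), 1L)
  # idempotent
  again <- filter_alignments(out)
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
  expect_equal(attr(again, "n_short") + attr(again, "n_mismatch") +
                 attr(again, "n_missing_mismatch"), 0L)
})

test_that("termination is inferred one base 5' of the alignment start", {
  expect_equal(infer_termination(make_reads(101, 180)), 100L)
  expect_equal(infer_termination(make_reads(1, 80)), 0L)   # runoff
  expect_equal(infer_termination(c(101L, 501L)), c(100L, 500L))
})

test_that("count accumulation applies coverage, primer exclusion and runoff rules", {
  primer <- list(name = "P1", start = 181L, end = 205L)
  tc <- accumulate_counts(make_reads(101, 180), primer, "treated", 300L)
  expect_equal(tc$n[100], 1)
  expect_equal(sum(tc$n), 1)
  # read-through counted where distance from annealing start exceeds 25 nt
  expect_equal(tc$r[101:155], rep(1, 55))
  expect_equal(tc$r[156:180], rep(0, 25))
  expect_true(all(tc$excluded[156:180]))
  expect_false(any(tc$excluded[101:155]))
  # no read contributes read-through at its own termination position
  expect_equal(tc$r[100], 0)
  # runoff read adds coverage but no termination
  tc2 <- accumulate_counts(make_reads(1, 180), primer, "treated", 300L)
  expect_equal(sum(tc2$n), 0)
  expect_equal(tc2$r[1], 1)

  none <- accumulate_counts(make_reads(integer(0), integer(0)), primer,
                            "treated", 300L)
  expect_equal(sum(none$n) + sum(none$r), 0)

  two <- accumulate_counts(make_reads(c(101, 101), c(180, 180)), primer,
                           "treated", 300L)
  expect_equal(two$n[100], 2)
})

test_that("counts are additive over read lists and multi-map weights sum to 1", {
  primer <- list(name = "P1", start = 281L, end = 300L)
  set.seed(11)
  starts <- sample(50:150, 40, replace = TRUE)
  reads <- make_reads(starts, starts + sample(60:120, 40, replace = TRUE))
  reads$end <- pmin(reads$end, 280L)
  a <- reads[1:15, ]; b <- reads[16:40, ]
  ca <- accumulate_counts(a, primer, "t", 300L)
  cb <- accumulate_counts(b, primer, "t", 300L)
  cab <- accumulate_counts(reads, primer, "t", 300L)
  expect_equal(cab$n, ca$n + cb$n)
  expect_equal(cab$r, ca$r + cb$r)

  # one read aligned at two sites, half weight each
  mm <- make_reads(c(101, 151), c(180, 230), weight = 0.5)
  cm <- accumulate_counts(mm, primer, "t", 300L)
  expect_equal(cm$n[100], 0.5)
  expect_equal(cm$n[150], 0.5)
  expect_equal(sum(cm$n), 1)
})

test_that("reads are assigned to the primer abutting their 3' end within slack", {
  panel <- primer_panel(data.frame(name = c("P1", "P2"),
                                   start = c(200, 900), end = c(219, 919),
                                   pool = c("A", "B")))
  reads <- make_reads(c(60, 760, 330), c(199, 896, 520))
  out <- assign_primers(reads, panel)
  expect_equal(out$primer, c("P1", "P2"))     # gaps 0 and 3 nt
  expect_equal(attr(out, "n_off_target"), 1L) # ends 380 nt before P2
})

test_that("SAM ingestion round-trips simulated reads including weights and filters", {
  cfg <- sim_config(length = 600L, reads_per_primer = 300L, seed = 5L)
  tx <- make_transcript(cfg)
  reads <- simulate_reads(tx, cfg, "treated")
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, tx$transcript, sam)
  back <- read_alignments(sam, tx$transcript)
  expect_equal(nrow(back), nrow(reads))
  expect_equal(sort(back$start), sort(reads$start))
  expect_equal(back$termination, back$start - 1L)
  expect_true(all(back$weight == 1))
  # identical counts through the file path and the in-memory path
  p1 <- tx$panel[1, ]
  direct <- accumulate_counts(reads[reads$primer == p1$name, ], p1, "t",
                              tx$transcript$length)
  assigned <- assign_primers(filter_alignments(back), tx$panel)
  viafile <- accumulate_counts(assigned[assigned$primer == p1$name, ], p1, "t",
                               tx$transcript$length)
  dir_f <- reads[reads$primer == p1$name & reads$aligned_len >= 60, ]
  direct_f <- accumulate_counts(dir_f, p1, "t", tx$transcript$length)
  expect_equal(viafile$n, direct_f$n)
  expect_equal(viafile$r, direct_f$r)
})

test_that("multi-mapped SAM records split weight by the NH tag", {
  sam <- tempfile(fileext = ".sam")
  L <- 400L
  seq61 <- paste(rep("A", 61), collapse = "")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:tx\tLN:%d", L),
               sprintf("r1\t0\ttx\t101\t255\t61M\t*\t0\t0\t%s\t*\tNM:i:0\tNH:i:2", seq61),
               sprintf("r1\t256\ttx\t301\t255\t61M\t*\t0\t0\t%s\t*\tNM:i:0\tNH:i:2", seq61),
               sprintf("r2\t0\ttx\t121\t255\t61M\t*\t0\t0\t%s\t*\tNM:i:0", seq61)),
             sam)
  tx <- transcript_ref("tx", paste(rep("A", L), collapse = ""))
  reads <- read_alignments(sam, tx)
  expect_equal(reads$weight, c(0.5, 0.5, 1))
  expect_equal(attr(reads, "n_no_multimap_info"), 1L)
  expect_equal(sum(reads$weight[reads$read_id == "r1"]), 1)
  expect_equal(reads$termination, c(100L, 300L, 120L))
})

test_that("primer panels flag close within-pool spacing but accept it", {
  expect_warning(primer_panel(data.frame(name = c("a", "b"),
                                         start = c(100, 400),
                                         end = c(119, 419),
                                         pool = "A")),
                 "500 nt")
  expect_silent(primer_panel(data.frame(name = c("a", "b"),
                                        start = c(100, 700),
                                        end = c(119, 719),
                                        pool = "A")))
})
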