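test_that("shuffling preserves composition and is reproducible under a seed", {
  expect_equal(shuffle_sequence("AAAA"), "AAAA")
  set.seed(4)
  s <- shuffle_sequence("ACGU")
  expect_equal(sort(strsplit(s, "")[[1]]), c("A", "C", "G", "U"))
  set.seed(99); a <- shuffle_sequence("ACGUACGUGGCCAAUU")
  set.seed(99); b <- shuffle_sequence("ACGUACGUGGCCAAUU")
  expect_identical(a, b)
  expect_error(shuffle_sequence(""), "empty")
})

test_that("dinucleotide shuffling preserves doublet composition", {
  seq <- "ACGUACGGCCAAUUGCA"
  doublets <- function(s) sort(substring(s, 1:(nchar(s) - 1), 2:nchar(s)))
  set.seed(12)
  s <- shuffle_sequence(seq, dinucleotide = TRUE)
  expect_equal(doublets(s), doublets(seq))
})

test_that("window z-scores follow the (native - mean) / sd formula", {
  # scripted energies: native -30; randomizations -25, -20, -15
  eng <- stub_engine(-30, c(-25, -20, -15))
  seq <- paste(rep("A", 150), collapse = "")
  sc <- zscore_scan(seq, eng, window = 150, step = 10, n_shuffles = 3)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$dg_random_mean, -20)
  expect_equal(sc$dg_random_sd, 5)
  expect_equal(sc$z, -2)
  # native equal to the shuffle mean gives z = 0
  expect_equal(zscore_scan(seq, stub_engine(-20, c(-25, -20, -15)),
                           window = 150, n_shuffles = 3)$z, 0)
})

test_that("z is invariant to adding a constant to every energy", {
  seq <- paste(rep("A", 150), collapse = "")
  z1 <- zscore_scan(seq, stub_engine(-30, c(-26, -21, -13)), window = 150,
                    n_shuffles = 3)$z
  z2 <- zscore_scan(seq, stub_engine(-30 + 7, c(-26, -21, -13) + 7),
                    window = 150, n_shuffles = 3)$z
  expect_equal(z1, z2)
})

test_that("unfoldable windows yield undefined z and the scan drops partial windows", {
  eng <- engine_builtin()
  seq <- paste(rep("A", 60), collapse = "")
  sc <- zscore_scan(seq, eng, window = 50, step = 10, n_shuffles = 5)
  expect_equal(sc$start, c(1, 11))     # start 21 would overrun: dropped
  expect_equal(sc$dg_native, c(0, 0))
  expect_true(all(is.na(sc$z)))        # all shuffle energies identical
})

test_that("scans are bit-reproducible for a fixed seed", {
  set.seed(31)
  seq <- paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE), collapse = "")
  eng <- engine_builtin()
  a <- zscore_scan(seq, eng, window = 60, step = 20, n_shuffles = 5, seed = 7)
  b <- zscore_scan(seq, eng, window = 60, step = 20, n_shuffles = 5, seed = 7)
  expect_identical(a, b)
})

test_that("region calling merges overlapping low-z windows by interval union", {
  sc <- data.frame(start = c(1, 11, 21, 301), end = c(150, 160, 170, 450),
                   dg_native = c(-30, -31, -29, -10),
                   dg_random_mean = 0, dg_random_sd = 1,
                   z = c(-3, -3.5, -2.6, -0.2), n_shuffles = 25L)
  reg <- call_regions(sc, cutoff = -2.19)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(1, 170))
  expect_equal(reg$z_min, -3.5)
  expect_equal(reg$z_mean, mean(c(-3, -3.5, -2.6)))
  expect_equal(reg$n_windows, 3L)
  # nothing below cutoff
  expect_equal(nrow(call_regions(sc, cutoff = -10)), 0L)
})

test_that("the automatic cutoff sits one population sd below the mean z", {
  sc <- data.frame(start = c(1, 11), end = c(150, 160),
                   dg_native = -20, dg_random_mean = 0, dg_random_sd = 1,
                   z = c(-0.83 - 1.36, -0.83 + 1.36), n_shuffles = 25L)
  reg <- call_regions(sc, cutoff = "auto")
  expect_equal(attr(reg, "cutoff"), -2.19)
})

test_that("abutting windows are separate regions unless gap_join allows", {
  sc <- data.frame(start = c(1, 200), end = c(150, 349),
                   dg_native = -30, dg_random_mean = 0, dg_random_sd = 1,
                   z = -3, n_shuffles = 25L)
  reg <- call_regions(sc, cutoff = -2)
  expect_equal(nrow(reg), 2L)
  joined <- call_regions(sc, cutoff = -2, gap_join = 49L)
  expect_equal(nrow(joined), 1L)
  expect_equal(c(joined$start, joined$end), c(1, 349))
})

test_that("region calling matches the brute-force interval union oracle", {
  set.seed(55)
  for (case in 1:60) {
    n_win <- sample(5:40, 1)
    starts <- sort(sample(1:500, n_win))
    w <- sample(c(20L, 50L), 1)
    sc <- data.frame(start = starts, end = starts + w - 1L,
                     dg_native = rnorm(n_win, -20), dg_random_mean = 0,
                     dg_random_sd = 1, z = rnorm(n_win, -1.5, 1),
                     n_shuffles = 25L)
    cutoff <- -1.5
    got <- call_regions(sc, cutoff = cutoff)
    want <- oracle_region_union(sc$start, sc$end, sc$z < cutoff)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("a more stringent cutoff never increases the called span", {
  set.seed(77)
  for (case in 1:20) {
    starts <- sort(sample(1:400, 25))
    sc <- data.frame(start = starts, end = starts + 49L, dg_native = -20,
                     dg_random_mean = 0, dg_random_sd = 1,
                     z = rnorm(25, -1.5, 1), n_shuffles = 25L)
    span <- function(cut) {
      r <- call_regions(sc, cutoff = cut)
      if (!nrow(r)) 0L else sum(r$end - r$start + 1L)
    }
    expect_true(span(-2.5) <= span(-1.5))
    expect_true(span(-1.5) <= span(-0.5))
  }
})

test_that("all-NA scans warn and return no regions", {
  sc <- data.frame(start = 1, end = 150, dg_native = 0, dg_random_mean = 0,
                   dg_random_sd = 0, z = NA_real_, n_shuffles = 25L)
  expect_warning(reg <- call_regions(sc), "undefined")
  expect_equal(nrow(reg), 0L)
})
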