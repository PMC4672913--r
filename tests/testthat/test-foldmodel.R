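eng <- engine_builtin()

test_that("strong-reactivity positions become constraints; NA never does", {
  prof <- make_profile(8, c(0, 0.002, 0, 0, 0.009, 0.008, NA, 0.0079), 500L)
  expect_equal(make_constraints(prof), c(5L, 6L))
  expect_equal(make_constraints(make_profile(4, rep(0.001, 4), 500L)), integer(0))
  na_prof <- make_profile(8, c(rep(0, 6), NA, 0), 500L)
  expect_equal(make_constraints(na_prof), integer(0))
})

test_that("the built-in engine folds a perfect stem-loop to its known MFE", {
  st <- mfe_fold("GGGGAAAACCCC", engine = eng)
  expect_equal(st$pairs, data.frame(i = 1:4, j = 12:9))
  # hand-summed: three GC-on-GC stacks plus a 4-nt hairpin loop
  p <- builtin_energy_params()
  hand <- 3 * p$stack["GC", "GC"] +
    round(100 * (p$hairpin_a + p$hairpin_b * log(4 / 3))) / 100
  expect_equal(st$energy, hand, tolerance = 1e-9)
  expect_equal(energy_of("GGGGAAAACCCC", st, eng), st$energy, tolerance = 0.01)
})

test_that("a modified position is excluded from helix-internal pairing only", {
  free <- mfe_fold("GGGGAAAACCCC", engine = eng)
  st <- mfe_fold("GGGGAAAACCCC", constraints = 2L, engine = eng)
  key <- paste(st$pairs$i, st$pairs$j)
  has_both_flanks <- ("1 12" %in% key) && ("3 10" %in% key) && ("2 11" %in% key)
  expect_false(has_both_flanks)
  expect_true(st$energy >= free$energy)
  expect_true(satisfies_constraints(st$pairs, 2L))
})

test_that("sequences without canonical pairs fold to the empty structure", {
  st <- mfe_fold("AAAA", engine = eng)
  expect_equal(nrow(st$pairs), 0L)
  expect_equal(st$energy, 0)
  expect_equal(energy_of("AAAA", st, eng), 0)
})

test_that("energy evaluation rejects non-canonical pairs with a listing", {
  st <- secondary_structure(10, data.frame(i = 1, j = 8))
  expect_error(energy_of("AAAAAAAAAA", st, eng), "1-8 \\(A:A\\)")
})

test_that("built-in MFE equals exhaustive enumeration on random sequences", {
  set.seed(101)
  for (case in 1:25) {
    n <- sample(8:14, 1)
    bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    seq <- paste(bases, collapse = "")
    cons <- if (case %% 2 == 0) sort(sample(n, 2)) else integer(0)
    got <- eng$fold(seq, cons)
    expect_equal(got$energy, oracle_mfe(seq, cons, eng), tolerance = 1e-9)
    expect_true(oracle_constraint_ok(cbind(got$pairs$i, got$pairs$j), cons))
  }
})

test_that("constraining can only raise the minimum free energy", {
  set.seed(202)
  for (case in 1:15) {
    bases <- sample(c("A", "C", "G", "U"), 30, replace = TRUE)
    seq <- paste(bases, collapse = "")
    free <- eng$fold(seq)$energy
    cons <- sort(sample(30, 4))
    expect_true(eng$fold(seq, cons)$energy >= free - 1e-9)
  }
})

test_that("dot-bracket and CT files round-trip structures losslessly", {
  set.seed(303)
  for (case in 1:5) {
    bases <- sample(c("A", "C", "G", "U"), 40, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2))
    seq <- paste(bases, collapse = "")
    st <- mfe_fold(seq, engine = eng, name = "toy")
    db <- pairs_to_dotbracket(st$pairs, st$length)
    expect_equal(dotbracket_to_pairs(db), st$pairs,
                 ignore_attr = TRUE)
    f1 <- tempfile(fileext = ".db")
    write_dotbracket(seq, st, f1)
    back <- read_dotbracket(f1)
    expect_equal(back$sequence, seq)
    expect_equal(back$structure$pairs, st$pairs)
    expect_equal(back$structure$energy, round(st$energy, 2))
    f2 <- tempfile(fileext = ".ct")
    write_ct(seq, st, f2)
    back2 <- read_ct(f2)
    expect_equal(back2$sequence, seq)
    expect_equal(back2$structure$pairs, st$pairs)
  }
})

test_that("constraint files round-trip in both dialects", {
  cons <- c(3L, 17L, 41L)
  f1 <- tempfile(); f2 <- tempfile()
  write_constraints(cons, f1, "list")
  write_constraints(cons, f2, "rnastructure")
  expect_equal(read_constraints(f1), cons)
  expect_equal(read_constraints(f2), cons)
  expect_true(any(grepl("^Mod:", readLines(f2))))
})

test_that("bootstrap support is 1 for every MFE pair when nothing varies", {
  seq <- "GGGGAAAACCCC"
  bs0 <- bootstrap_support(seq, integer(0), eng, n = 20, seed = 3)
  mfe <- eng$fold(seq)$pairs
  expect_equal(nrow(bs0), nrow(mfe))
  expect_true(all(bs0$support == 1))
  # fraction 1: all replicates use the full constraint set
  bs1 <- bootstrap_support(seq, c(2L, 6L), eng, n = 20, fraction = 1, seed = 3)
  full <- eng$fold(seq, c(2L, 6L))$pairs
  sup_full <- merge(full, bs1, by = c("i", "j"))
  expect_equal(nrow(sup_full), nrow(full))
  expect_true(all(sup_full$support == 1))
})

test_that("bootstrap support maps are deterministic and quantized by 1/n", {
  seq <- "GGGGAAAACCCC"
  a <- bootstrap_support(seq, c(2L, 6L), eng, n = 50, seed = 11)
  b <- bootstrap_support(seq, c(2L, 6L), eng, n = 50, seed = 11)
  expect_identical(a, b)
  expect_true(all(abs(a$support * 50 - round(a$support * 50)) < 1e-9))
  expect_true(all(a$consensus == (a$support > 0.5)))
  expect_error(bootstrap_support(seq, c(2L), eng, n = 0), "at least 1")
})

test_that("the Vienna adapter folds and evaluates but refuses constraints", {
  v <- engine_vienna()
  res <- v$fold("GGGGAAAACCCC")
  expect_equal(nrow(res$pairs), 4L)
  expect_equal(v$eval("GGGGAAAACCCC", res$pairs), res$energy, tolerance = 0.011)
  expect_equal(v$fold_energies(c("GGGGAAAACCCC", "AAAAAAAAAA")),
               c(res$energy, 0))
  expect_error(mfe_fold("GGGGAAAACCCC", constraints = 2L, engine = v),
               "engine_builtin")
})

test_that("subsetting a profile re-indexes positions to the fragment", {
  prof <- make_profile(10, c(rep(0, 4), 0.01, 0.002, 0.009, rep(0, 3)), 500L)
  sub <- subset_profile(prof, 5, 8)
  expect_equal(sub$position, 1:4)
  expect_equal(make_constraints(sub), c(1L, 3L))
})
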