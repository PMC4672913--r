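# Independent oracles used by the tests. These deliberately do not call the
# package's own algorithms beyond the energy function under audit.

# All nested structures over `bases` with canonical pairs and a minimum
# hairpin loop of 3 nt, as a list of 2-column pair matrices.
enum_pairsets <- function(bases) {
  rec <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(), ncol = 2)))
    out <- rec(i + 1, j)
    for (k in (i + 4):j) {
      if (is_canonical_pair(bases[i], bases[k])) {
        inner <- rec(i + 1, k - 1); outer <- rec(k + 1, j)
        for (a in inner) for (b in outer)
          out <- c(out, list(rbind(c(i, k), a, b)))
      }
    }
    out
  }
  rec(1, length(bases))
}

# Chemical-modification predicate, restated from first principles: a flagged
# position may not sit in a pair with both (i-1, j+1) and (i+1, j-1) paired.
oracle_constraint_ok <- function(mat, constraints) {
  if (!length(constraints) || !nrow(mat)) return(TRUE)
  key <- paste(mat[, 1], mat[, 2])
  for (k in seq_len(nrow(mat))) {
    i <- mat[k, 1]; j <- mat[k, 2]
    if (!(i %in% constraints || j %in% constraints)) next
    if (paste(i + 1, j - 1) %in% key && paste(i - 1, j + 1) %in% key)
      return(FALSE)
  }
  TRUE
}

# Brute-force MFE by exhaustive enumeration, scored with the engine's own
# energy function (itself checked against hand summation elsewhere).
oracle_mfe <- function(seq, constraints, engine) {
  bases <- strsplit(seq, "")[[1]]
  structs <- enum_pairsets(bases)
  best <- Inf
  for (m in structs) {
    if (!oracle_constraint_ok(m, constraints)) next
    e <- engine$eval(seq, list(i = m[, 1], j = m[, 2]))
    if (e < best) best <- e
  }
  best
}

# Brute-force union of below-cutoff window intervals: sort and sweep,
# merging intervals that share at least one position (abutting intervals
# remain separate).
oracle_region_union <- function(starts, ends, hit) {
  s <- starts[hit]; e <- ends[hit]
  if (!length(s)) return(data.frame(start = integer(), end = integer()))
  o <- order(s); s <- s[o]; e <- e[o]
  rs <- s[1]; re <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(s)[-1]) {
    if (s[k] <= re) {
      re <- max(re, e[k])
    } else {
      out_s <- c(out_s, rs); out_e <- c(out_e, re)
      rs <- s[k]; re <- e[k]
    }
  }
  data.frame(start = c(out_s, rs), end = c(out_e, re))
}

# Mann-Whitney AUC: probability a positive outranks a negative.
rank_auc <- function(score, positive) {
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

# Tiny aligned-read set builder with the pipeline's column contract.
make_reads <- function(start, end, weight = 1, mismatches = 0L,
                       primer = NA_character_, transcript = "tx") {
  n <- length(start)
  structure(data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    transcript = rep_len(transcript, n),
    start = as.integer(start), end = as.integer(end),
    aligned_len = as.integer(end - start + 1L),
    mismatches = as.integer(rep_len(mismatches, n)),
    weight = rep_len(weight, max(n, 0L)),
    termination = as.integer(start - 1L),
    primer = rep_len(primer, n),
    stringsAsFactors = FALSE),
    class = c("aligned_reads", "data.frame"))
}

# Stub engine returning scripted energies: the first sequence of a batch
# (the native window) gets `native`, shuffles cycle through `randoms`.
stub_engine <- function(native, randoms) {
  structure(list(
    name = "stub",
    fold_energies = function(sequences)
      c(native, rep_len(randoms, length(sequences) - 1L))),
    class = "folding_engine")
}

# Minimal per-primer reactivity profile for combine_primers tests.
make_profile <- function(L, p_dms, primer_start, r = 2000) {
  structure(data.frame(position = seq_len(L), p_term = p_dms, p_spont = 0,
                       p_dms = p_dms, r_treated = rep_len(r, L),
                       r_untreated = rep_len(r, L),
                       coverage_ok = !is.na(p_dms)),
            class = c("reactivity_profile", "data.frame"),
            primer = paste0("P", primer_start), primer_start = primer_start,
            transcript = "tx")
}
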