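#' Build folding constraints from a reactivity profile
#'
#' Positions with strong DMS reactivity (`p_dms >= threshold`, default
#' 0.8%) and adequate coverage are flagged as chemically modified. During
#' constrained folding such positions may not occupy a Watson-Crick pair
#' flanked on both sides by Watson-Crick pairs (helix-internal position);
#' helix-terminal pairing and unpaired states remain allowed. NA positions
#' are never constrained. The profile must already be indexed to the
#' folded fragment (position 1 = fragment 5' end).
#'
#' @param profile a `reactivity_profile` on the folded fragment.
#' @param threshold reactivity threshold (default 0.008).
#' @return sorted integer vector of constrained positions.
#' @export
make_constraints <- function(profile, threshold = 0.008) {
  sort(profile$position[!is.na(profile$p_dms) & profile$p_dms >= threshold])
}

#' Re-index a reactivity profile to a subsequence
#'
#' Extracts positions `from:to` and renumbers them 1..(to-from+1) so the
#' profile can constrain folding of that fragment.
#'
#' @param profile a `reactivity_profile` on the full transcript.
#' @param from,to 1-based inclusive fragment bounds.
#' @return the re-indexed `reactivity_profile`.
#' @export
subset_profile <- function(profile, from, to) {
  out <- profile[profile$position >= from & profile$position <= to, , drop = FALSE]
  out$position <- out$position - from + 1L
  rownames(out) <- NULL
  out
}

#' Minimum free energy folding with chemical-modification constraints
#'
#' Folds the sequence at 37 degrees C under the engine's nearest-neighbor
#' model, honoring the chemical-modification constraint semantics (flagged
#' positions may not be helix-internal). The constrained MFE is never more
#' favorable than the unconstrained MFE.
#'
#' @param seq RNA string.
#' @param constraints integer vector of modified positions (default none).
#' @param engine a [folding_engine] (default [engine_builtin()]).
#' @param name transcript name for the returned structure.
#' @return a [secondary_structure] with energy attached.
#' @export
mfe_fold <- function(seq, constraints = integer(0), engine = engine_builtin(),
                     name = "transcript") {
  seq <- toupper(gsub("T", "U", seq))
  if (!nchar(seq)) stop("empty sequence")
  if (length(constraints) &&
      (min(constraints) < 1L || max(constraints) > nchar(seq)))
    stop("constraint position outside the sequence")
  res <- engine$fold(seq, modified = as.integer(constraints))
  secondary_structure(nchar(seq), res$pairs, name = name, energy = res$energy)
}

#' Free energy of a given structure
#'
#' Thermodynamic evaluation of a (possibly hand-built) structure under the
#' engine's energy model; no refolding. Pairs between non-complementary
#' bases are an error listing the offending pairs.
#'
#' @param seq RNA string.
#' @param structure a [secondary_structure] valid for `seq`.
#' @param engine a [folding_engine] (default [engine_builtin()]).
#' @return energy in kcal/mol.
#' @export
energy_of <- function(seq, structure, engine = engine_builtin()) {
  seq <- toupper(gsub("T", "U", seq))
  if (nchar(seq) != structure$length)
    stop("sequence length does not match structure")
  if (nrow(structure$pairs)) {
    bases <- strsplit(seq, "")[[1]]
    bad <- !is_canonical_pair(bases[structure$pairs$i], bases[structure$pairs$j])
    if (any(bad))
      stop("non-canonical pairs in structure: ",
           paste(sprintf("%d-%d (%s:%s)", structure$pairs$i[bad],
                         structure$pairs$j[bad], bases[structure$pairs$i[bad]],
                         bases[structure$pairs$j[bad]]), collapse = ", "))
  }
  engine$eval(seq, structure$pairs)
}

#' Check a structure against the chemical-modification constraint
#'
#' TRUE when no flagged position sits in a pair flanked on both sides by
#' pairs (i.e. with both `(i-1, j+1)` and `(i+1, j-1)` paired with each
#' other).
#'
#' @param pairs data.frame of pairs `i`, `j`.
#' @param constraints integer vector of flagged positions.
#' @return logical scalar.
#' @export
satisfies_constraints <- function(pairs, constraints) {
  if (!length(constraints) || !nrow(pairs)) return(TRUE)
  key <- paste(pairs$i, pairs$j)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!(i %in% constraints || j %in% constraints)) next
    inner <- paste(i + 1L, j - 1L) %in% key
    outer <- paste(i - 1L, j + 1L) %in% key
    if (inner && outer) return(FALSE)
  }
  TRUE
}

#' Bootstrap support of base pairs under constraint subsampling
#'
#' Refolds the sequence `n` times, each time using a random subset of
#' `ceiling(fraction * |constraints|)` constraints sampled without
#' replacement, and reports the fraction of replicates in which each pair
#' appears. Consensus pairs are those with support > 0.5. With an empty
#' constraint set every replicate is identical, so all MFE pairs have
#' support 1. Identical constraint subsets are folded once and reused.
#'
#' @param seq RNA string.
#' @param constraints integer vector of modified positions.
#' @param engine a [folding_engine] (default [engine_builtin()]).
#' @param n number of replicates (default 1000).
#' @param fraction subset fraction (default 0.5).
#' @param seed integer seed.
#' @return a `bootstrap_support` object: data.frame with columns `i`, `j`,
#'   `support`, `consensus`; attributes `n`, `fraction`, `seed`.
#' @export
bootstrap_support <- function(seq, constraints = integer(0),
                              engine = engine_builtin(), n = 1000L,
                              fraction = 0.5, seed = 1L) {
  if (n < 1L) stop("n must be at least 1")
  seq <- toupper(gsub("T", "U", seq))
  constraints <- sort(as.integer(constraints))
  m <- ceiling(fraction * length(constraints))
  set.seed(as.integer(seed))
  tally <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  for (rep_k in seq_len(n)) {
    sub <- if (length(constraints)) sort(sample(constraints, m)) else integer(0)
    key <- paste0("k", paste(sub, collapse = ","))
    pairs <- if (!is.null(cache[[key]])) cache[[key]] else {
      p <- engine$fold(seq, modified = sub)$pairs
      cache[[key]] <- p
      p
    }
    if (nrow(pairs)) {
      for (pk in paste(pairs$i, pairs$j)) {
        tally[[pk]] <- if (is.null(tally[[pk]])) 1L else tally[[pk]] + 1L
      }
    }
  }
  keys <- ls(tally)
  if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, " "))
    df <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                     support = vapply(keys, function(k) tally[[k]], integer(1)) / n)
  } else {
    df <- data.frame(i = integer(), j = integer(), support = numeric())
  }
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df$consensus <- df$support > 0.5
  structure(df, class = c("bootstrap_support", "data.frame"),
            n = as.integer(n), fraction = fraction, seed = as.integer(seed),
            n_constraints = length(constraints), subset_size = m)
}

#' Write folding constraints to a file
#'
#' `format = "list"` writes one 1-based position per line. `format =
#' "rnastructure"` writes the chemical-modification section of the
#' RNAstructure-style constraint dialect (Mod: block).
#'
#' @param constraints integer vector of positions.
#' @param file output path.
#' @param format `"list"` or `"rnastructure"`.
#' @export
write_constraints <- function(constraints, file, format = c("list", "rnastructure")) {
  format <- match.arg(format)
  constraints <- sort(as.integer(constraints))
  if (format == "list") {
    writeLines(as.character(constraints), file)
  } else {
    writeLines(c("DS:", "-1", "SS:", "-1", "Mod:",
                 as.character(constraints), "-1",
                 "Pairs:", "-1 -1", "FMN:", "-1", "Forbids:", "-1 -1"),
               file)
  }
  invisible(file)
}

#' Read folding constraints from a file
#'
#' Accepts the plain position-list format and the RNAstructure-style
#' dialect written by [write_constraints()] (Mod: block).
#'
#' @param file input path.
#' @return sorted integer vector of positions.
#' @export
read_constraints <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  if (any(grepl("^Mod:", lines))) {
    i0 <- which(grepl("^Mod:", lines))[1] + 1L
    out <- integer(0)
    while (i0 <= length(lines) && lines[i0] != "-1") {
      out <- c(out, as.integer(lines[i0]))
      i0 <- i0 + 1L
    }
    return(sort(out))
  }
  sort(as.integer(lines))
}
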