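#' Load a multiple sequence alignment block
#'
#' Reads an aligned FASTA or Clustal alignment (via Biostrings) and
#' prepares it for base-pair conservation analysis against a designated
#' reference row. T is converted to U; the gap character is `-`.
#'
#' @param file path to the alignment.
#' @param reference name of the reference row (default: first row).
#' @param format `"fasta"` or `"clustal"`.
#' @return an `alignment_block`: list with `seqs` (character matrix, rows =
#'   species), `reference`, `ref_map` (ungapped reference position ->
#'   alignment column).
#' @export
read_alignment <- function(file, reference = NULL,
                           format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readBStringSet(file, format = format)
  alignment_block(stats::setNames(as.character(aln), names(aln)), reference)
}

#' Construct an alignment block from named sequences
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   over A, C, G, U/T and `-`.
#' @param reference name of the reference row (default: first).
#' @return an `alignment_block`.
#' @export
alignment_block <- function(seqs, reference = NULL) {
  seqs <- toupper(gsub("T", "U", seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows have unequal lengths")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named")
  if (is.null(reference)) reference <- names(seqs)[1]
  if (!reference %in% names(seqs)) stop("reference row not found: ", reference)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  ref_map <- which(mat[reference, ] != "-")
  structure(list(seqs = mat, reference = reference, ref_map = ref_map),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("Alignment block:", nrow(x$seqs), "rows x", ncol(x$seqs), "columns;",
      "reference:", x$reference,
      sprintf("(%d ungapped nt)\n", length(x$ref_map)))
  invisible(x)
}

#' Subset alignment rows
#'
#' Keeps the named rows (the reference is always retained), e.g. to score
#' a rodent-only subset of a mammalian alignment.
#'
#' @param aln an `alignment_block`.
#' @param rows character vector of row names to keep.
#' @return an `alignment_block`.
#' @export
subset_alignment <- function(aln, rows) {
  rows <- union(aln$reference, rows)
  missing <- setdiff(rows, rownames(aln$seqs))
  if (length(missing)) stop("rows not in alignment: ", paste(missing, collapse = ", "))
  seqs <- apply(aln$seqs[rows, , drop = FALSE], 1, paste, collapse = "")
  alignment_block(seqs, aln$reference)
}

#' Map model base pairs to alignment columns
#'
#' Each reference pair `(i, j)` (1-based ungapped reference coordinates)
#' is mapped to its alignment columns through the reference row's gap
#' structure. The mapping is injective; pairs beyond the reference's
#' ungapped length are an error.
#'
#' @param structure a [secondary_structure] on the ungapped reference.
#' @param aln an `alignment_block`.
#' @return data.frame with columns `i`, `j` (reference positions),
#'   `col_i`, `col_j` (alignment columns).
#' @export
map_pairs <- function(structure, aln) {
  n_ref <- length(aln$ref_map)
  pr <- structure$pairs
  if (nrow(pr) && max(pr$j) > n_ref)
    stop("structure position ", max(pr$j), " beyond the reference's ",
         n_ref, " ungapped nt")
  data.frame(i = pr$i, j = pr$j,
             col_i = aln$ref_map[pr$i], col_j = aln$ref_map[pr$j])
}

.pair_status <- function(a, b) {
  # per-species status of one column pair
  ifelse(a == "-" | b == "-", "gapped",
         ifelse(paste0(a, b) %in% .canonical_pairs, "canonical", "non_canonical"))
}

#' Score base-pair conservation over an alignment
#'
#' For each model pair, every species' residues at the mapped columns are
#' classified as canonical (AU, UA, CG, GC and GU/UG wobble),
#' non-canonical, or gapped (a gap in either residue; counted as
#' non-canonical in the fraction). The canonical fraction is taken over
#' all rows including the reference; model conservation is the mean over
#' pairs.
#'
#' @param aln an `alignment_block`.
#' @param column_pairs data.frame from [map_pairs()].
#' @return a `pair_conservation` data.frame with per-pair
#'   `canonical_fraction`; the mean conservation (percent) is in attribute
#'   `conservation_pct`.
#' @export
score_pair_conservation <- function(aln, column_pairs) {
  if (nrow(column_pairs) &&
      max(column_pairs$col_j) > ncol(aln$seqs))
    stop("column beyond alignment width")
  frac <- vapply(seq_len(nrow(column_pairs)), function(k) {
    a <- aln$seqs[, column_pairs$col_i[k]]
    b <- aln$seqs[, column_pairs$col_j[k]]
    mean(.pair_status(a, b) == "canonical")
  }, numeric(1))
  out <- cbind(column_pairs, canonical_fraction = frac)
  structure(out, class = c("pair_conservation", "data.frame"),
            conservation_pct = 100 * mean(frac),
            n_species = nrow(aln$seqs))
}

#' Classify consistent and compensatory mutations
#'
#' Per pair and species (against the reference row): a mutation is
#' *consistent* when exactly one residue differs from the reference and
#' the species pair is still canonical; *compensatory* when both residues
#' differ and the pair is still canonical. The two classes are disjoint
#' per species per pair. Per-pair flags record whether any species shows
#' the class; summary counts are the number of pairs with each flag.
#'
#' @param aln an `alignment_block`.
#' @param column_pairs data.frame from [map_pairs()].
#' @return a `pair_conservation` data.frame with columns
#'   `n_consistent_species`, `n_compensatory_species`, `has_consistent`,
#'   `has_compensatory`; summary counts in attributes `n_pairs_consistent`
#'   and `n_pairs_compensatory`.
#' @export
classify_mutations <- function(aln, column_pairs) {
  ref <- aln$reference
  res <- lapply(seq_len(nrow(column_pairs)), function(k) {
    a <- aln$seqs[, column_pairs$col_i[k]]
    b <- aln$seqs[, column_pairs$col_j[k]]
    ra <- a[ref]; rb <- b[ref]
    canonical <- .pair_status(a, b) == "canonical"
    ndiff <- (a != ra) + (b != rb)
    others <- rownames(aln$seqs) != ref
    consistent <- others & canonical & ndiff == 1L & a != "-" & b != "-"
    compensatory <- others & canonical & ndiff == 2L & a != "-" & b != "-"
    c(sum(consistent), sum(compensatory))
  })
  res <- do.call(rbind, res)
  out <- cbind(column_pairs,
               n_consistent_species = res[, 1],
               n_compensatory_species = res[, 2],
               has_consistent = res[, 1] > 0L,
               has_compensatory = res[, 2] > 0L)
  structure(out, class = c("pair_conservation", "data.frame"),
            n_pairs_consistent = sum(res[, 1] > 0L),
            n_pairs_compensatory = sum(res[, 2] > 0L))
}

#' Full base-pair conservation report for a structure model
#'
#' Combines [map_pairs()], [score_pair_conservation()] and
#' [classify_mutations()] into the per-pair table and model-level summary
#' (number of pairs, mean conservation percent, counts of pairs with
#' consistent and compensatory mutations).
#'
#' @param structure a [secondary_structure] on the ungapped reference.
#' @param aln an `alignment_block`.
#' @return a `pair_conservation` data.frame; summary in attribute
#'   `summary` (data.frame with `bps`, `conservation_pct`, `consistent`,
#'   `compensatory`).
#' @export
conservation_report <- function(structure, aln) {
  cp <- map_pairs(structure, aln)
  cons <- score_pair_conservation(aln, cp)
  mut <- classify_mutations(aln, cp)
  out <- cbind(cons,
               mut[, c("n_consistent_species", "n_compensatory_species",
                       "has_consistent", "has_compensatory")])
  structure(out, class = c("pair_conservation", "data.frame"),
            summary = data.frame(
              bps = nrow(cp),
              conservation_pct = attr(cons, "conservation_pct"),
              consistent = attr(mut, "n_pairs_consistent"),
              compensatory = attr(mut, "n_pairs_compensatory")))
}

#' Write a per-pair conservation report as TSV
#'
#' @param report a `pair_conservation` from [conservation_report()].
#' @param file output path.
#' @export
write_conservation_tsv <- function(report, file) {
  utils::write.table(as.data.frame(report), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
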