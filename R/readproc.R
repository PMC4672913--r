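#' Load a probed transcript from FASTA
#'
#' The transcript is stored as RNA (T is converted to U on load) with
#' 1-based coordinates.
#'
#' @param fasta path to a FASTA file.
#' @param name optional record name; default is the first record.
#' @return an object of class `transcript_ref` with fields `name`,
#'   `sequence`, `length`.
#' @export
load_transcript <- function(fasta, name = NULL) {
  set <- Biostrings::readBStringSet(fasta)
  if (!length(set)) stop("no records in ", fasta)
  idx <- 1L
  if (!is.null(name)) {
    idx <- match(name, sub("\\s.*", "", names(set)))
    if (is.na(idx)) stop("record not found in FASTA: ", name)
  }
  transcript_ref(sub("\\s.*", "", names(set)[idx]), as.character(set[[idx]]))
}

#' Construct a transcript reference
#'
#' @param name transcript identifier.
#' @param sequence RNA or DNA string; T is converted to U, alphabet must be
#'   ACGU after conversion.
#' @return a `transcript_ref`.
#' @export
transcript_ref <- function(name, sequence) {
  sequence <- toupper(gsub("T", "U", sequence))
  if (grepl("[^ACGU]", sequence))
    stop("transcript alphabet restricted to ACGU (after T->U conversion)")
  structure(list(name = name, sequence = sequence, length = nchar(sequence)),
            class = "transcript_ref")
}

#' @export
print.transcript_ref <- function(x, ...) {
  cat("Transcript", x$name, "-", x$length, "nt (RNA)\n")
  invisible(x)
}

#' Read an RT-primer panel from a TSV file
#'
#' Tab-separated columns: `name`, `start`, `end` (1-based inclusive
#' annealing interval on the transcript), `pool`, `adaptor`.
#'
#' @param file path to the TSV.
#' @param transcript optional `transcript_ref` for bounds checking.
#' @return a `primer_panel` data.frame.
#' @export
read_primer_panel <- function(file, transcript = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  primer_panel(df, transcript)
}

#' Construct an RT-primer panel
#'
#' Primers within one pool closer than 500 nt trigger a warning (they risk
#' interfering with reverse-transcriptase elongation), not an error.
#'
#' @param df data.frame with columns `name`, `start`, `end`, `pool` and
#'   optionally `adaptor`.
#' @param transcript optional `transcript_ref` for bounds checking.
#' @return a `primer_panel` data.frame.
#' @export
primer_panel <- function(df, transcript = NULL) {
  need <- c("name", "start", "end", "pool")
  if (!all(need %in% names(df)))
    stop("primer panel needs columns: ", paste(need, collapse = ", "))
  if (!"adaptor" %in% names(df))
    df$adaptor <- rep("CAGACGTGTGCTCT", nrow(df))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("primer interval with start > end")
  if (!is.null(transcript) && any(df$end > transcript$length | df$start < 1L))
    stop("primer interval outside transcript bounds")
  for (p in unique(df$pool)) {
    s <- sort(df$start[df$pool == p])
    if (length(s) > 1L && any(diff(s) < 500L))
      warning("primers within pool '", p, "' are < 500 nt apart")
  }
  class(df) <- c("primer_panel", "data.frame")
  df
}

#' Clip the leading random-mer from raw reads
#'
#' Removes exactly `clip` leading bases (the NNN introduced by the
#' 3'-adaptor) from each read; qualities are clipped in lockstep and read
#' order is preserved. Reads shorter than `clip + 1` nt are skipped and
#' counted.
#'
#' @param reads character vector of read sequences.
#' @param qualities optional character vector of quality strings.
#' @param clip number of leading bases to remove (default 3).
#' @return list with `reads`, `qualities` (NULL if not supplied) and
#'   `n_skipped`.
#' @export
clip_reads <- function(reads, qualities = NULL, clip = 3L) {
  keep <- nchar(reads) >= clip + 1L
  out <- substring(reads[keep], clip + 1L)
  qout <- if (!is.null(qualities)) substring(qualities[keep], clip + 1L) else NULL
  list(reads = out, qualities = qout, n_skipped = sum(!keep))
}

#' Clip the leading random-mer from a FASTQ file
#'
#' File-based version of [clip_reads()]; parsing and writing go through
#' Biostrings.
#'
#' @param infile input FASTQ path.
#' @param outfile output FASTQ path.
#' @param clip number of leading bases to remove (default 3).
#' @return number of reads skipped as too short (invisibly, also emitted as
#'   a message).
#' @export
clip_fastq <- function(infile, outfile, clip = 3L) {
  # Biostrings warns that per-read metadata columns are dropped during
  # construction/narrowing; none are used downstream
  suppressWarnings({
    reads <- Biostrings::readQualityScaledDNAStringSet(infile)
    keep <- Biostrings::width(reads) >= clip + 1L
    n_skipped <- sum(!keep)
    clipped <- IRanges::narrow(reads[keep], start = clip + 1L)
    Biostrings::writeQualityScaledXStringSet(clipped, outfile)
  })
  if (n_skipped > 0)
    message(n_skipped, " read(s) shorter than ", clip + 1L, " nt skipped")
  invisible(n_skipped)
}

# reference span of a cigar minus deletions/introns = aligned length;
# soft/hard clips and insertions consume no reference
.cigar_stats <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    len <- as.integer(sub("[MIDNSHP=X]", "", o))
    op <- sub("[0-9]+", "", o)
    ref_span <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    aligned <- sum(len[op %in% c("M", "=", "X")])
    c(ref_span, aligned)
  }, numeric(2))
}

#' Read aligned RT-stop reads from a SAM/BAM file
#'
#' Parses alignment records via Rsamtools (SAM input is converted to BAM in
#' a temporary file first). Produces one row per alignment with the
#' coordinate conventions of the RT-stop pipeline: the inferred termination
#' position is `start - 1` (the RNA base the reverse transcriptase failed
#' to copy; 0 denotes runoff past position 1). Multi-mapped reads (NH tag
#' k > 1) carry weight 1/k; a missing NH tag is treated as unique and
#' counted in `n_no_multimap_info`.
#'
#' @param file SAM or BAM path.
#' @param transcript optional `transcript_ref`; alignments to other
#'   references or outside its bounds are dropped and tallied.
#' @return an `aligned_reads` data.frame with columns `read_id`,
#'   `transcript`, `start`, `end`, `aligned_len`, `mismatches`, `weight`,
#'   `termination`, `primer`; attributes carry drop tallies.
#' @export
read_alignments <- function(file, transcript = NULL) {
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("NM", "NH"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(rec$flag, 4L) & !is.na(rec$pos)
  n_unmapped <- sum(!mapped)
  stats <- .cigar_stats(rec$cigar[mapped])
  n_mapped <- sum(mapped)
  mm <- if (is.null(rec$tag$NM)) rep(NA_integer_, n_mapped) else rec$tag$NM[mapped]
  df <- data.frame(
    read_id = rec$qname[mapped],
    transcript = as.character(rec$rname[mapped]),
    start = rec$pos[mapped],
    end = rec$pos[mapped] + as.integer(stats[1, ]) - 1L,
    aligned_len = as.integer(stats[2, ]),
    mismatches = mm,
    stringsAsFactors = FALSE)
  nh <- if (is.null(rec$tag$NH)) rep(NA_integer_, nrow(df)) else rec$tag$NH[mapped]
  n_no_multimap_info <- sum(is.na(nh))
  nh[is.na(nh)] <- 1L
  df$weight <- 1 / nh
  n_out_of_bounds <- 0L
  if (!is.null(transcript)) {
    ok <- df$transcript == transcript$name & df$start >= 1L &
      df$end <= transcript$length
    n_out_of_bounds <- sum(!ok)
    df <- df[ok, , drop = FALSE]
  }
  df$termination <- df$start - 1L
  df$primer <- rep(NA_character_, nrow(df))
  rownames(df) <- NULL
  structure(df,
            class = c("aligned_reads", "data.frame"),
            n_unmapped = n_unmapped,
            n_out_of_bounds = n_out_of_bounds,
            n_no_multimap_info = n_no_multimap_info)
}

#' Filter alignments by length and mismatches
#'
#' Retains reads with aligned length >= `min_len` and at most
#' `max_mismatch` mismatches. Records without a mismatch count are
#' discarded under a distinct tally. The operation is idempotent.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param min_len minimum aligned length in nt (default 60).
#' @param max_mismatch maximum mismatch count (default 2).
#' @return filtered `aligned_reads`; attributes `n_short`, `n_mismatch`,
#'   `n_missing_mismatch` tally the discards.
#' @export
filter_alignments <- function(reads, min_len = 60L, max_mismatch = 2L) {
  missing_mm <- is.na(reads$mismatches)
  short <- !missing_mm & reads$aligned_len < min_len
  many <- !missing_mm & !short & reads$mismatches > max_mismatch
  keep <- !missing_mm & !short & !many
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = class(reads),
            n_short = sum(short),
            n_mismatch = sum(many),
            n_missing_mismatch = sum(missing_mm))
}

#' Infer the RT termination position of aligned reads
#'
#' The reverse transcriptase, walking 3' to 5' along the RNA, stops one
#' base short of a blocking position: the inferred termination is
#' `start - 1`, the RNA base it failed to copy. A value of 0 denotes
#' full-length runoff past position 1 and contributes no termination count.
#'
#' @param reads an `aligned_reads` data.frame (or integer vector of 5'-most
#'   aligned positions).
#' @return integer vector of termination positions.
#' @export
infer_termination <- function(reads) {
  if (is.data.frame(reads)) reads$start - 1L else as.integer(reads) - 1L
}

#' Assign reads to RT primers
#'
#' Each read is assigned to the primer whose annealing interval overlaps or
#' abuts the read's 3'-cDNA end (its rightmost aligned position) within
#' `slack` nt. Ties go to the nearest annealing start. Unassignable reads
#' are off-target: they are dropped and tallied.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param panel a `primer_panel`.
#' @param slack maximum gap in nt between read end and annealing start
#'   (default 5).
#' @return `aligned_reads` with the `primer` column filled; attribute
#'   `n_off_target` tallies drops.
#' @export
assign_primers <- function(reads, panel, slack = 5L) {
  primer <- rep(NA_character_, nrow(reads))
  best_gap <- rep(Inf, nrow(reads))
  for (k in seq_len(nrow(panel))) {
    ps <- panel$start[k]; pe <- panel$end[k]
    gap <- ps - 1L - reads$end           # nt between read end and annealing start
    ok <- reads$end <= pe & gap <= slack
    better <- ok & abs(gap) < best_gap
    primer[better] <- panel$name[k]
    best_gap[better] <- abs(gap[better])
  }
  keep <- !is.na(primer)
  out <- reads[keep, , drop = FALSE]
  out$primer <- primer[keep]
  rownames(out) <- NULL
  structure(out, class = class(reads), n_off_target = sum(!keep))
}

#' Accumulate termination and read-through counts for one primer
#'
#' For every transcript position `i`, `n(i)` is the summed weight of reads
#' terminating at `i` (runoff reads with termination 0 are excluded) and
#' `r(i)` is the summed weight of reads whose alignment interval covers
#' `i`. Positions within `primer_exclusion` nt of the primer's
#' annealing-proximal end are excluded from read-through counting
#' (`r = 0`, flagged), protecting the annealing site from analysis; the
#' rule is strict (distance > `primer_exclusion` kept).
#'
#' @param reads `aligned_reads` already filtered and assigned to `primer`.
#' @param primer one-row subset of a `primer_panel` (or a list with `name`,
#'   `start`, `end`).
#' @param condition condition label, e.g. `"treated"` or `"untreated"`.
#' @param transcript_length transcript length in nt.
#' @param primer_exclusion exclusion distance in nt (default 25).
#' @return a `termination_counts` data.frame with columns `position`, `n`,
#'   `r`, `excluded`; attributes `condition`, `primer`, `n_out_of_bounds`.
#' @export
accumulate_counts <- function(reads, primer, condition, transcript_length,
                              primer_exclusion = 25L) {
  L <- as.integer(transcript_length)
  ok <- reads$start >= 1L & reads$end <= L
  n_oob <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  n <- numeric(L)
  term <- reads$termination
  has_term <- term >= 1L
  if (any(has_term)) {
    agg <- tapply(reads$weight[has_term], term[has_term], sum)
    n[as.integer(names(agg))] <- agg
  }
  # weighted coverage by difference array
  cov <- numeric(L + 1L)
  for (k in seq_len(nrow(reads))) {
    cov[reads$start[k]] <- cov[reads$start[k]] + reads$weight[k]
    cov[reads$end[k] + 1L] <- cov[reads$end[k] + 1L] - reads$weight[k]
  }
  r <- cumsum(cov)[seq_len(L)]
  pos <- seq_len(L)
  excluded <- (primer$start - pos) <= primer_exclusion & pos < primer$start
  excluded <- excluded | (pos >= primer$start)   # annealing site itself and beyond
  r[excluded] <- 0
  structure(data.frame(position = pos, n = n, r = r, excluded = excluded),
            class = c("termination_counts", "data.frame"),
            condition = condition, primer = primer$name,
            primer_start = primer$start, primer_end = primer$end,
            n_out_of_bounds = n_oob)
}

#' Count terminations and read-throughs for a whole panel
#'
#' Runs [assign_primers()] and [accumulate_counts()] for every primer in
#' the panel and returns one `termination_counts` per primer.
#'
#' @param reads filtered `aligned_reads`.
#' @param panel a `primer_panel`.
#' @param condition condition label.
#' @param transcript_length transcript length in nt.
#' @param primer_exclusion exclusion distance in nt (default 25).
#' @param slack primer-assignment slack in nt (default 5).
#' @return named list of `termination_counts`, one per primer.
#' @export
count_terminations <- function(reads, panel, condition, transcript_length,
                               primer_exclusion = 25L, slack = 5L) {
  assigned <- assign_primers(reads, panel, slack = slack)
  out <- lapply(seq_len(nrow(panel)), function(k) {
    sub <- assigned[assigned$primer == panel$name[k], , drop = FALSE]
    accumulate_counts(sub, panel[k, ], condition, transcript_length,
                      primer_exclusion)
  })
  names(out) <- panel$name
  out
}

#' Write termination counts as TSV
#'
#' Columns: transcript, position, condition, primer, n, r, excluded_flag.
#'
#' @param counts list of `termination_counts` (or a single one).
#' @param transcript transcript name.
#' @param file output path.
#' @export
write_counts_tsv <- function(counts, transcript, file) {
  if (inherits(counts, "termination_counts")) counts <- list(counts)
  rows <- lapply(counts, function(tc)
    data.frame(transcript = transcript, position = tc$position,
               condition = attr(tc, "condition"), primer = attr(tc, "primer"),
               n = tc$n, r = tc$r, excluded_flag = as.integer(tc$excluded)))
  utils::write.table(do.call(rbind, rows), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
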