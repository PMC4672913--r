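#' Configuration for a synthetic probing experiment
#'
#' Defines the study conditions the simulator emulates: a transcript with
#' planted stem-loops, per-position modification probabilities, and
#' treated/untreated RT read sets generated by a per-position hazard walk.
#' Defaults reflect a realistic targeted probing experiment: strong sites
#' terminate the RT with probability ~1% per encounter (around the strong
#' reactivity threshold), spontaneous drop-off is 0.2% per nt, RT products
#' shorter than 100 nt are lost during library construction, primers are
#' spaced ~200 nt apart, and each primer yields 10^4 reads.
#'
#' @param length transcript length in nt (ignored when `sequence` given).
#' @param sequence explicit RNA sequence (optional).
#' @param planted_structure explicit [secondary_structure] (optional; by
#'   default stem-loops are planted while generating the sequence).
#' @param p_hit per-encounter termination probability at accessible
#'   (unpaired) A/C under treatment.
#' @param p_bg termination probability at protected positions under
#'   treatment.
#' @param p_spont per-nt spontaneous drop-off probability (both
#'   conditions).
#' @param dose_scale multiplier on `p_hit`/`p_bg` (DMS dose).
#' @param ac_only when TRUE (default) G/U positions are never modified,
#'   matching DMS chemistry.
#' @param min_recovered_length RT products shorter than this are lost
#'   (default 100 nt).
#' @param reads_per_primer reads simulated per primer and condition.
#' @param primer_spacing distance between primer annealing starts.
#' @param primer_width annealing interval width.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(length = 2000L, sequence = NULL,
                       planted_structure = NULL,
                       p_hit = 0.01, p_bg = 5e-4, p_spont = 2e-3,
                       dose_scale = 1, ac_only = TRUE,
                       min_recovered_length = 100L,
                       reads_per_primer = 10000L,
                       primer_spacing = 200L, primer_width = 20L,
                       seed = 1L) {
  probs <- c(p_hit = p_hit, p_bg = p_bg, p_spont = p_spont)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (min_recovered_length >= primer_spacing + primer_width)
    stop("min_recovered_length must be smaller than the primer spacing")
  structure(list(length = as.integer(length), sequence = sequence,
                 planted_structure = planted_structure,
                 p_hit = p_hit, p_bg = p_bg, p_spont = p_spont,
                 dose_scale = dose_scale, ac_only = ac_only,
                 min_recovered_length = as.integer(min_recovered_length),
                 reads_per_primer = as.integer(reads_per_primer),
                 primer_spacing = as.integer(primer_spacing),
                 primer_width = as.integer(primer_width),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.rand_bases <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

.revcomp_rna <- function(chars) rev(c(A = "U", C = "G", G = "C", U = "A")[chars])

#' Generate the synthetic transcript, planted structure and ground truth
#'
#' Without an explicit sequence, the transcript is tiled with stem-loop
#' modules (8-12 bp stems, 5-7 nt A/C-rich loops) separated by random
#' linkers, so a known set of unpaired A/C positions is accessible.
#' Ground-truth modification probability is `p_hit * dose_scale` at
#' accessible (unpaired) A/C, `p_bg * dose_scale` at paired A/C, and 0 at
#' G/U when `ac_only` (DMS methylates only A and C).
#'
#' @param cfg a [sim_config()].
#' @return list with `transcript` ([transcript_ref]), `structure`
#'   ([secondary_structure]), `panel` ([primer_panel]), `truth`
#'   (data.frame: `position`, `base`, `paired`, `accessible`, `p_mod`).
#' @export
make_transcript <- function(cfg) {
  set.seed(cfg$seed)
  if (is.null(cfg$sequence)) {
    chars <- character(0)
    pairs_i <- integer(0); pairs_j <- integer(0)
    pos <- 0L
    while (pos < cfg$length) {
      linker <- sample(10:20, 1)
      chars <- c(chars, .rand_bases(linker)); pos <- pos + linker
      stem <- sample(8:12, 1)
      loop <- sample(5:7, 1)
      if (pos + 2L * stem + loop + 10L > cfg$length) {
        # pad out with unstructured sequence
        if (cfg$length > pos) chars <- c(chars, .rand_bases(cfg$length - pos))
        pos <- cfg$length
        break
      }
      left <- .rand_bases(stem)
      loop_seq <- sample(c("A", "C"), loop, replace = TRUE)
      right <- .revcomp_rna(left)
      pairs_i <- c(pairs_i, pos + seq_len(stem))
      pairs_j <- c(pairs_j, pos + 2L * stem + loop + 1L - seq_len(stem))
      chars <- c(chars, left, loop_seq, right)
      pos <- pos + 2L * stem + loop
    }
    seq <- paste(chars[seq_len(cfg$length)], collapse = "")
    keep <- pairs_j <= cfg$length
    st <- secondary_structure(cfg$length,
                              data.frame(i = pairs_i[keep], j = pairs_j[keep]),
                              name = "sim_transcript")
  } else {
    seq <- toupper(gsub("T", "U", cfg$sequence))
    if (is.null(cfg$planted_structure))
      stop("an explicit sequence needs an explicit planted structure")
    st <- cfg$planted_structure
    bases <- strsplit(seq, "")[[1]]
    bad <- !is_canonical_pair(bases[st$pairs$i], bases[st$pairs$j])
    if (any(bad)) stop("planted structure inconsistent with sequence complementarity")
  }
  tr <- transcript_ref("sim_transcript", seq)
  bases <- strsplit(tr$sequence, "")[[1]]
  paired <- rep(FALSE, tr$length)
  paired[c(st$pairs$i, st$pairs$j)] <- TRUE
  is_ac <- bases %in% c("A", "C")
  accessible <- !paired & is_ac
  p_mod <- ifelse(accessible, cfg$p_hit, cfg$p_bg) * cfg$dose_scale
  if (cfg$ac_only) p_mod[!is_ac] <- 0
  truth <- data.frame(position = seq_len(tr$length), base = bases,
                      paired = paired, accessible = accessible, p_mod = p_mod)
  if (tr$length >= cfg$primer_spacing + cfg$primer_width) {
    starts <- seq.int(cfg$primer_spacing, tr$length - cfg$primer_width,
                      by = cfg$primer_spacing)
  } else {
    starts <- integer(0)
  }
  panel <- suppressWarnings(primer_panel(data.frame(
    name = sprintf("P%02d", seq_along(starts)),
    start = starts, end = starts + cfg$primer_width - 1L,
    pool = rep_len(c("A", "B", "C"), length(starts)),
    stringsAsFactors = FALSE), tr))
  list(transcript = tr, structure = st, panel = panel, truth = truth)
}

#' Simulate RT reads for one condition
#'
#' The reverse transcriptase starts just 5' of each primer's annealing
#' interval and walks 3' to 5' along the template; at each position it
#' terminates with probability `p_spont` plus (for the treated condition)
#' the position's modification probability, capped at 1. The per-read
#' termination position is therefore multinomial with exactly computable
#' probabilities, which the simulator samples directly. Products shorter
#' than `min_recovered_length` are lost; runoff reads reach position 1.
#'
#' @param truth the list from [make_transcript()].
#' @param cfg the [sim_config()].
#' @param condition `"treated"` or `"untreated"`.
#' @param seed integer seed (default derived from `cfg$seed` and the
#'   condition).
#' @return an `aligned_reads` data.frame (weight 1, 0 mismatches) with
#'   the generating primer recorded.
#' @export
simulate_reads <- function(truth, cfg, condition = c("treated", "untreated"),
                           seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(seed))
    seed <- cfg$seed + if (condition == "treated") 104729L else 224737L
  set.seed(as.integer(seed))
  p_mod <- if (condition == "treated") truth$truth$p_mod else
    numeric(nrow(truth$truth))
  hazard <- pmin(1, cfg$p_spont + p_mod)
  panel <- truth$panel
  all_reads <- list()
  for (k in seq_len(nrow(panel))) {
    ps <- panel$start[k]
    first <- ps - 1L                       # first extended template position
    walk <- first:1L                       # template positions in walk order
    h <- hazard[walk]
    surv <- cumprod(1 - h)
    # P(terminate at walk position m) = h[m] * prod_{<m}(1 - h)
    p_term <- h * c(1, surv[-length(surv)])
    p_runoff <- surv[length(surv)]
    counts <- stats::rmultinom(1, cfg$reads_per_primer, c(p_term, p_runoff))[, 1]
    term_pos <- c(walk, 0L)                # 0 = runoff past position 1
    nz <- which(counts > 0L)
    t_vec <- rep(term_pos[nz], counts[nz])
    a <- t_vec + 1L
    b <- rep(first, length(a))
    len <- b - a + 1L
    keep <- len >= cfg$min_recovered_length
    if (!any(keep)) next
    all_reads[[k]] <- data.frame(
      read_id = sprintf("%s_%s_%06d", condition, panel$name[k],
                        seq_len(sum(keep))),
      transcript = truth$transcript$name,
      start = a[keep], end = b[keep], aligned_len = len[keep],
      mismatches = 0L, weight = 1,
      termination = t_vec[keep], primer = panel$name[k],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, all_reads)
  if (is.null(out))
    out <- data.frame(read_id = character(), transcript = character(),
                      start = integer(), end = integer(),
                      aligned_len = integer(), mismatches = integer(),
                      weight = numeric(), termination = integer(),
                      primer = character())
  rownames(out) <- NULL
  structure(out, class = c("aligned_reads", "data.frame"),
            condition = condition, seed = as.integer(seed))
}

#' Write simulated reads as a SAM file
#'
#' Minimal single-end records aligned to the plus strand of the
#' transcript: full-length match CIGAR, MAPQ 255, tags `NM:i:0` and
#' `NH:i:1`, so the SAM ingestion path can be exercised end to end.
#'
#' @param reads an `aligned_reads` data.frame from [simulate_reads()].
#' @param transcript the [transcript_ref] the reads derive from.
#' @param file output SAM path.
#' @export
write_sam <- function(reads, transcript, file) {
  dna <- chartr("U", "T", transcript$sequence)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", transcript$name, transcript$length))
  body <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:1",
                  reads$read_id, reads$transcript, reads$start,
                  reads$aligned_len,
                  substring(dna, reads$start, reads$end),
                  reads$mismatches)
  writeLines(c(header, body), file)
  invisible(file)
}

#' Run a complete synthetic experiment
#'
#' Generates the transcript and both read sets, then runs the counting and
#' reactivity stages, returning everything needed for parameter-recovery
#' checks against the planted ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `transcript`, `structure`, `panel`, `truth`,
#'   `reads_treated`, `reads_untreated`, `counts_treated`,
#'   `counts_untreated`, `profiles` (per primer) and `combined`
#'   (combined `reactivity_profile`).
#' @export
sim_experiment <- function(cfg = sim_config()) {
  tx <- make_transcript(cfg)
  rt <- simulate_reads(tx, cfg, "treated")
  ru <- simulate_reads(tx, cfg, "untreated")
  ct <- count_terminations(rt, tx$panel, "treated", tx$transcript$length)
  cu <- count_terminations(ru, tx$panel, "untreated", tx$transcript$length)
  profiles <- lapply(names(ct), function(p) compute_pdms(ct[[p]], cu[[p]]))
  combined <- combine_primers(profiles)
  c(tx, list(reads_treated = rt, reads_untreated = ru,
             counts_treated = ct, counts_untreated = cu,
             profiles = profiles, combined = combined))
}
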