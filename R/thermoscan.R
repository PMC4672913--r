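#' Shuffle a sequence preserving composition
#'
#' Uniform random permutation of the characters (mononucleotide shuffle:
#' identical composition, order randomized). Uses the current R RNG, so
#' results are reproducible under `set.seed()`. A dinucleotide-preserving
#' shuffle (Altschul-Erikson style Eulerian walk) is available as an
#' option.
#'
#' @param seq RNA string.
#' @param dinucleotide preserve dinucleotide composition (default FALSE;
#'   the z-score scan compares against same-composition randomizations).
#' @return shuffled string.
#' @export
shuffle_sequence <- function(seq, dinucleotide = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  if (!length(chars)) stop("cannot shuffle an empty sequence")
  if (!dinucleotide)
    return(paste(sample(chars), collapse = ""))
  # dinucleotide shuffle: random walk over the doublet graph until the
  # walk uses every edge and ends at the original last character
  n <- length(chars)
  if (n < 3L) return(paste(chars, collapse = ""))
  for (attempt in 1:200) {
    edges <- split(chars[-1], chars[-n])
    edges <- lapply(edges, sample)
    out <- character(n); out[1] <- chars[1]
    ok <- TRUE
    for (k in 2:n) {
      pool <- edges[[out[k - 1]]]
      if (is.null(pool) || !length(pool)) { ok <- FALSE; break }
      out[k] <- pool[1]
      edges[[out[k - 1]]] <- pool[-1]
    }
    if (ok) return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to complete a walk")
}

.pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Sliding-window thermodynamic z-score scan
#'
#' Slides a `window`-nt window in steps of `step` nt over the transcript.
#' For each window the native minimum free energy is compared with
#' `n_shuffles` same-composition randomizations:
#' `z = (dG_native - mean(dG_random)) / sd(dG_random)`.
#' Strongly negative z marks windows whose sequence is more stable than
#' its composition predicts — the signature of evolved structure. The
#' final partial window (when `length - window` is not a multiple of
#' `step`) is dropped. Shuffle RNG streams are derived per window from
#' `(seed, window start)` so scans are reproducible and order-independent.
#' An engine failure on a window yields an NA z for that window; the scan
#' continues.
#'
#' @param seq RNA string (length >= `window`).
#' @param engine a [folding_engine] (see [engine_builtin()],
#'   [engine_vienna()]).
#' @param window window size in nt (default 150).
#' @param step step in nt (default 10).
#' @param n_shuffles randomizations per window (default 25).
#' @param seed integer seed for the shuffle streams.
#' @param dinucleotide use dinucleotide-preserving shuffles (default FALSE).
#' @return a `window_scores` data.frame with columns `start`, `end`,
#'   `dg_native`, `dg_random_mean`, `dg_random_sd`, `z`, `n_shuffles`.
#' @export
zscore_scan <- function(seq, engine, window = 150L, step = 10L,
                        n_shuffles = 25L, seed = 1L, dinucleotide = FALSE) {
  seq <- toupper(gsub("T", "U", seq))
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than one window")
  starts <- seq.int(1L, L - window + 1L, by = step)
  rows <- lapply(starts, function(s) {
    frag <- substr(seq, s, s + window - 1L)
    res <- tryCatch({
      # per-window RNG stream: reproducible and parallelizable
      set.seed((as.integer(seed) %% 100000L) * 20011L + s)
      shuf <- vapply(seq_len(n_shuffles), function(k)
        shuffle_sequence(frag, dinucleotide), character(1))
      e <- engine$fold_energies(c(frag, shuf))
      dgn <- e[1]; dgr <- e[-1]
      m <- mean(dgr); sdev <- stats::sd(dgr)
      z <- if (is.na(sdev) || sdev == 0) NA_real_ else (dgn - m) / sdev
      c(dgn, m, sdev, z)
    }, error = function(e) {
      warning("window ", s, ": ", conditionMessage(e))
      rep(NA_real_, 4)
    })
    data.frame(start = s, end = s + window - 1L, dg_native = res[1],
               dg_random_mean = res[2], dg_random_sd = res[3], z = res[4])
  })
  out <- do.call(rbind, rows)
  out$n_shuffles <- as.integer(n_shuffles)
  structure(out, class = c("window_scores", "data.frame"),
            window = as.integer(window), step = as.integer(step),
            seed = as.integer(seed))
}

#' Call structured regions from window z-scores
#'
#' Windows with `z < cutoff` whose intervals overlap (share at least one
#' nt) are merged by interval union. With `cutoff = "auto"` the cutoff is
#' `mean(z) - sd(z)` over all non-NA windows (population sd), i.e. one
#' standard deviation more favorable than the transcript average.
#' `gap_join` optionally merges called regions separated by at most that
#' many nt (default 0 = off; joining adjacent domains is a curation step,
#' not the default behavior).
#'
#' @param scores a `window_scores` data.frame from [zscore_scan()].
#' @param cutoff numeric cutoff or `"auto"`.
#' @param gap_join merge regions separated by <= `gap_join` nt (default 0).
#' @return a `structured_regions` data.frame with columns `start`, `end`,
#'   `z_mean`, `z_min`, `dg_mean`, `dg_min`, `n_windows`; the applied
#'   cutoff is carried as an attribute.
#' @export
call_regions <- function(scores, cutoff = "auto", gap_join = 0L) {
  usable <- !is.na(scores$z)
  if (!any(usable)) {
    warning("all windows have undefined z; no regions called")
    return(structure(data.frame(start = integer(), end = integer(),
                                z_mean = numeric(), z_min = numeric(),
                                dg_mean = numeric(), dg_min = numeric(),
                                n_windows = integer()),
                     class = c("structured_regions", "data.frame"),
                     cutoff = NA_real_))
  }
  if (identical(cutoff, "auto"))
    cutoff <- mean(scores$z[usable]) - .pop_sd(scores$z)
  hit <- usable & scores$z < cutoff
  empty <- structure(data.frame(start = integer(), end = integer(),
                                z_mean = numeric(), z_min = numeric(),
                                dg_mean = numeric(), dg_min = numeric(),
                                n_windows = integer()),
                     class = c("structured_regions", "data.frame"),
                     cutoff = cutoff)
  if (!any(hit)) return(empty)
  ir <- IRanges::IRanges(start = scores$start[hit], end = scores$end[hit])
  merged <- IRanges::reduce(ir, min.gapwidth = 0L)       # overlap only
  if (gap_join > 0L)
    merged <- IRanges::reduce(merged, min.gapwidth = gap_join + 1L)
  hs <- scores[hit, , drop = FALSE]
  rows <- lapply(seq_along(merged), function(k) {
    rs <- IRanges::start(merged)[k]; re <- IRanges::end(merged)[k]
    member <- hs$start <= re & hs$end >= rs
    data.frame(start = rs, end = re,
               z_mean = mean(hs$z[member]), z_min = min(hs$z[member]),
               dg_mean = mean(hs$dg_native[member]),
               dg_min = min(hs$dg_native[member]),
               n_windows = sum(member))
  })
  structure(do.call(rbind, rows),
            class = c("structured_regions", "data.frame"), cutoff = cutoff)
}

#' Write window scores as TSV
#'
#' @param scores a `window_scores` data.frame.
#' @param file output path.
#' @export
write_windows_tsv <- function(scores, file) {
  utils::write.table(as.data.frame(scores), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Write structured regions as TSV
#'
#' Coordinates are 1-based inclusive; columns mirror the per-region
#' summary (average and minimum z, average and minimum window free
#' energy).
#'
#' @param regions a `structured_regions` data.frame.
#' @param file output path.
#' @export
write_regions_tsv <- function(regions, file) {
  out <- as.data.frame(regions)
  names(out) <- c("start_1based", "end_1based", "z_avg", "z_min",
                  "dG_avg", "dG_min", "n_windows")
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
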