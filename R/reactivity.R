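#' Per-base DMS reactivity from termination counts
#'
#' Estimates the probability that base `i` is modified by DMS as the excess
#' termination rate in the treated sample over the spontaneous rate in the
#' untreated control:
#' `P_term(i) = n_T(i)/r_T(i)`, `P_spont(i) = n_U(i)/r_U(i)`,
#' `P_DMS(i) = P_term(i) - P_spont(i)`.
#' Positions with zero read-through in either condition are NA with a
#' coverage flag. Negative values are retained (not clamped).
#'
#' @param treated,untreated `termination_counts` for the same transcript
#'   and primer (condition labels are carried in attributes).
#' @param transcript optional transcript name consistency check; when both
#'   counts carry a `transcript` attribute and they differ, an error is
#'   raised.
#' @return a `reactivity_profile` data.frame with columns `position`,
#'   `p_term`, `p_spont`, `p_dms`, `r_treated`, `r_untreated`, `coverage_ok`;
#'   primer metadata is carried in attributes.
#' @export
compute_pdms <- function(treated, untreated, transcript = NULL) {
  tt <- attr(treated, "transcript"); tu <- attr(untreated, "transcript")
  if (!is.null(tt) && !is.null(tu) && !identical(tt, tu))
    stop("termination counts are for different transcripts: ", tt, " vs ", tu)
  if (!identical(attr(treated, "primer"), attr(untreated, "primer")))
    stop("termination counts are for different primers")
  if (nrow(treated) != nrow(untreated))
    stop("termination counts have different lengths")
  ok <- treated$r > 0 & untreated$r > 0
  p_term <- ifelse(treated$r > 0, treated$n / treated$r, NA_real_)
  p_spont <- ifelse(untreated$r > 0, untreated$n / untreated$r, NA_real_)
  p_dms <- ifelse(ok, p_term - p_spont, NA_real_)
  structure(data.frame(position = treated$position,
                       p_term = p_term, p_spont = p_spont, p_dms = p_dms,
                       r_treated = treated$r, r_untreated = untreated$r,
                       coverage_ok = ok),
            class = c("reactivity_profile", "data.frame"),
            primer = attr(treated, "primer"),
            primer_start = attr(treated, "primer_start"),
            transcript = if (!is.null(tt)) tt else tu)
}

#' Combine per-primer reactivity profiles
#'
#' A primer is eligible at a position when the position lies `window[1]` to
#' `window[2]` nt (inclusive) from the primer's annealing start and the
#' position's read-through exceeds `min_readthrough` in both the treated
#' and untreated samples. The combined reactivity is the arithmetic mean of
#' `p_dms` over eligible primers; positions with no eligible primer are NA.
#'
#' @param profiles list of per-primer `reactivity_profile`s (from
#'   [compute_pdms()], carrying `primer_start` attributes).
#' @param window inclusive distance range from the primer in nt
#'   (default `c(100, 380)`).
#' @param min_readthrough read-through events required in both conditions
#'   (strict, default 1000).
#' @return a combined `reactivity_profile` with columns `position`,
#'   `p_dms`, `n_primers`.
#' @export
combine_primers <- function(profiles, window = c(100L, 380L),
                            min_readthrough = 1000) {
  L <- unique(vapply(profiles, nrow, integer(1)))
  if (length(L) != 1L)
    stop("per-primer profiles have inconsistent transcript lengths")
  acc <- numeric(L); nelig <- integer(L)
  for (pr in profiles) {
    ps <- attr(pr, "primer_start")
    if (is.null(ps)) stop("profile lacks primer annealing coordinates")
    d <- ps - pr$position
    elig <- d >= window[1] & d <= window[2] &
      pr$r_treated > min_readthrough & pr$r_untreated > min_readthrough &
      !is.na(pr$p_dms)
    acc[elig] <- acc[elig] + pr$p_dms[elig]
    nelig[elig] <- nelig[elig] + 1L
  }
  p <- ifelse(nelig > 0L, acc / pmax(nelig, 1L), NA_real_)
  structure(data.frame(position = seq_len(L), p_dms = p, n_primers = nelig,
                       coverage_ok = nelig > 0L),
            class = c("reactivity_profile", "data.frame"),
            transcript = attr(profiles[[1]], "transcript"))
}

#' Classify per-base reactivity
#'
#' Strong reactivity: `p_dms >= strong` (default 0.8%); moderate:
#' `moderate < p_dms < strong` (strict bounds, default 0.4%); low
#' otherwise. NA positions (insufficient coverage) stay NA. Non-NA
#' positions are partitioned into exactly one class.
#'
#' @param profile a `reactivity_profile`.
#' @param strong,moderate thresholds on `p_dms`.
#' @return the profile with an added `class` factor column.
#' @export
classify_reactivity <- function(profile, strong = 0.008, moderate = 0.004) {
  cls <- rep(NA_character_, nrow(profile))
  p <- profile$p_dms
  cls[!is.na(p) & p >= strong] <- "strong"
  cls[!is.na(p) & p > moderate & p < strong] <- "moderate"
  cls[!is.na(p) & p <= moderate] <- "low"
  profile$class <- factor(cls, levels = c("strong", "moderate", "low"))
  profile
}

#' A+C specificity of top-ranked reactive positions
#'
#' DMS methylates accessible A and C; ranking positions by reactivity and
#' asking what fraction of the top ranks are A or C is the standard
#' specificity control. Positions are sorted by descending `p_dms`, ties
#' broken by ascending position (deterministic output); NA positions are
#' not ranked.
#'
#' @param profile a `reactivity_profile`.
#' @param transcript a `transcript_ref` congruent with the profile.
#' @param ranks integer vector of rank cutoffs.
#' @return data.frame with columns `rank` and `ac_fraction`.
#' @export
ac_specificity <- function(profile, transcript, ranks) {
  if (nrow(profile) != transcript$length)
    stop("profile and transcript lengths differ")
  def <- profile[!is.na(profile$p_dms), , drop = FALSE]
  ord <- def[order(-def$p_dms, def$position), , drop = FALSE]
  bases <- strsplit(transcript$sequence, "")[[1]]
  is_ac <- bases[ord$position] %in% c("A", "C")
  ranks <- pmin(as.integer(ranks), nrow(ord))
  data.frame(rank = ranks,
             ac_fraction = vapply(ranks, function(k)
               if (k < 1L) NA_real_ else mean(is_ac[seq_len(k)]), numeric(1)))
}

#' Agreement between two reactivity profiles
#'
#' Pearson correlation and least-squares slope (of `p2` on `p1`) over
#' positions with defined, non-zero reactivity in both profiles — the
#' inter-primer / inter-condition quality control.
#'
#' @param p1,p2 `reactivity_profile`s on the same transcript.
#' @return list with `r`, `slope`, `n` (positions compared).
#' @export
compare_profiles <- function(p1, p2) {
  if (nrow(p1) != nrow(p2)) stop("profiles are not on the same transcript")
  ok <- !is.na(p1$p_dms) & !is.na(p2$p_dms) & p1$p_dms != 0 & p2$p_dms != 0
  if (sum(ok) < 3L) {
    warning("fewer than 3 co-defined non-zero positions; agreement undefined")
    return(list(r = NA_real_, slope = NA_real_, n = sum(ok)))
  }
  x <- p1$p_dms[ok]; y <- p2$p_dms[ok]
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y), slope = unname(stats::coef(fit)[2]), n = sum(ok))
}

#' Write a reactivity profile as TSV
#'
#' Columns: transcript, position, base, P_term, P_spont, P_DMS, n_primers,
#' class (fields absent from the profile are written as NA).
#'
#' @param profile a `reactivity_profile`.
#' @param transcript a `transcript_ref`.
#' @param file output path.
#' @export
write_reactivity_tsv <- function(profile, transcript, file) {
  bases <- strsplit(transcript$sequence, "")[[1]]
  get <- function(col) if (col %in% names(profile)) profile[[col]] else NA
  out <- data.frame(transcript = transcript$name,
                    position = profile$position,
                    base = bases[profile$position],
                    P_term = get("p_term"), P_spont = get("p_spont"),
                    P_DMS = profile$p_dms,
                    n_primers = get("n_primers"),
                    class = as.character(get("class")))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
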