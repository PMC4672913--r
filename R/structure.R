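#' RNA secondary structure container
#'
#' A nested (pseudoknot-free) secondary structure over a 1-based transcript:
#' a pair list with `i < j`, each position in at most one pair, and a minimum
#' hairpin loop of 3 unpaired nucleotides (`j - i >= 4`).
#'
#' @param length transcript length in nt.
#' @param pairs data.frame with integer columns `i`, `j` (1-based, `i < j`).
#' @param name transcript name.
#' @param energy optional free energy in kcal/mol.
#' @return an object of class `secondary_structure`.
#' @export
secondary_structure <- function(length, pairs = data.frame(i = integer(), j = integer()),
                                name = "transcript", energy = NULL) {
  pairs <- as.data.frame(pairs)[, c("i", "j")]
  pairs$i <- as.integer(pairs$i)
  pairs$j <- as.integer(pairs$j)
  if (nrow(pairs)) {
    swap <- pairs$i > pairs$j
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
    pairs <- pairs[order(pairs$i), , drop = FALSE]
    rownames(pairs) <- NULL
    if (any(pairs$i < 1L) || any(pairs$j > length))
      stop("pair positions outside [1, length]")
    if (anyDuplicated(c(pairs$i, pairs$j)))
      stop("a position occurs in more than one pair")
    if (any(pairs$j - pairs$i < 4L))
      stop("hairpin loop shorter than 3 unpaired nt (j - i < 4)")
    # nestedness: no crossing pairs
    if (nrow(pairs) > 1L) {
      for (k in seq_len(nrow(pairs) - 1L)) {
        crosses <- pairs$i > pairs$i[k] & pairs$i < pairs$j[k] & pairs$j > pairs$j[k]
        if (any(crosses)) stop("crossing (pseudoknotted) pairs are not allowed")
      }
    }
  }
  structure(list(name = name, length = as.integer(length), pairs = pairs,
                 energy = energy),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure:", x$name, "\n")
  cat("  length:", x$length, "nt;", nrow(x$pairs), "base pairs\n")
  if (!is.null(x$energy)) cat("  energy:", sprintf("%.2f kcal/mol", x$energy), "\n")
  if (x$length <= 120) cat(" ", pairs_to_dotbracket(x$pairs, x$length), "\n")
  invisible(x)
}

#' Convert a pair list to a dot-bracket string
#'
#' @param pairs data.frame with columns `i`, `j`.
#' @param length transcript length.
#' @return a dot-bracket string of `length` characters.
#' @export
pairs_to_dotbracket <- function(pairs, length) {
  db <- rep(".", length)
  if (nrow(pairs)) {
    db[pairs$i] <- "("
    db[pairs$j] <- ")"
  }
  paste(db, collapse = "")
}

#' Convert a dot-bracket string to a pair list
#'
#' @param db dot-bracket string (characters `.`, `(`, `)`).
#' @return data.frame with columns `i`, `j`.
#' @export
dotbracket_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  open <- integer(0)
  i <- integer(0); j <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      i <- c(i, open[length(open)])
      j <- c(j, k)
      open <- open[-length(open)]
    } else if (chars[k] != ".") {
      stop("unexpected character in dot-bracket string: ", chars[k])
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  data.frame(i = i, j = j)[order(i), , drop = FALSE]
}

#' Read a secondary structure from a dot-bracket file
#'
#' Expects an optional FASTA-style header line, a sequence line, and a
#' dot-bracket line (an appended energy in parentheses is tolerated).
#'
#' @param file path to a dot-bracket file.
#' @return list with `sequence` and a `secondary_structure`.
#' @export
read_dotbracket <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  name <- "transcript"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  seq <- toupper(gsub("T", "U", trimws(lines[1])))
  db <- trimws(lines[2])
  energy <- NULL
  m <- regmatches(db, regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)$", db))[[1]]
  if (length(m)) {
    db <- m[2]
    energy <- as.numeric(m[3])
  }
  if (nchar(db) != nchar(seq)) stop("sequence and structure lengths differ")
  list(sequence = seq,
       structure = secondary_structure(nchar(seq), dotbracket_to_pairs(db),
                                       name = name, energy = energy))
}

#' Write a secondary structure as a dot-bracket file
#'
#' @param sequence RNA sequence string.
#' @param structure a `secondary_structure`.
#' @param file output path.
#' @export
write_dotbracket <- function(sequence, structure, file) {
  db <- pairs_to_dotbracket(structure$pairs, structure$length)
  line <- if (!is.null(structure$energy))
    sprintf("%s (%.2f)", db, structure$energy) else db
  writeLines(c(paste0(">", structure$name), sequence, line), file)
}

#' Read a secondary structure from a CT file
#'
#' Standard 6-column connectivity table: index, base, previous, next,
#' pairing partner (0 = unpaired), natural numbering.
#'
#' @param file path to a CT file.
#' @return list with `sequence` and a `secondary_structure`.
#' @export
read_ct <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[1])
  name <- if (length(header) > 1) paste(header[-1], collapse = " ") else "transcript"
  energy <- NULL
  em <- regmatches(name, regexec("(ENERGY|dG)\\s*=?\\s*(-?[0-9.]+)", name))[[1]]
  if (length(em)) energy <- as.numeric(em[3])
  body <- do.call(rbind, lapply(lines[2:(n + 1)], function(l)
    strsplit(trimws(l), "\\s+")[[1]][1:5]))
  bases <- body[, 2]
  partner <- as.integer(body[, 5])
  seq <- paste(toupper(gsub("T", "U", bases)), collapse = "")
  keep <- which(partner > seq_len(n))
  pairs <- data.frame(i = keep, j = partner[keep])
  list(sequence = seq,
       structure = secondary_structure(n, pairs, name = name, energy = energy))
}

#' Write a secondary structure as a CT file
#'
#' @param sequence RNA sequence string.
#' @param structure a `secondary_structure`.
#' @param file output path.
#' @export
write_ct <- function(sequence, structure, file) {
  n <- structure$length
  if (nchar(sequence) != n) stop("sequence length does not match structure")
  partner <- integer(n)
  partner[structure$pairs$i] <- structure$pairs$j
  partner[structure$pairs$j] <- structure$pairs$i
  bases <- strsplit(sequence, "")[[1]]
  header <- if (!is.null(structure$energy))
    sprintf("%d ENERGY = %.2f %s", n, structure$energy, structure$name)
  else sprintf("%d %s", n, structure$name)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                  seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L), partner, seq_len(n))
  writeLines(c(header, rows), file)
}

# canonical pair lookup shared across modules: AU, UA, CG, GC, GU, UG
.canonical_pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Test whether two bases form a canonical pair (including GU wobble)
#'
#' @param a,b single upper-case RNA bases.
#' @return logical vector.
#' @export
is_canonical_pair <- function(a, b) {
  paste0(a, b) %in% .canonical_pairs
}
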