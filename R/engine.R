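#' Folding engine interface
#'
#' A folding engine is a list with class `folding_engine` providing
#' `fold(sequence, modified)` (MFE structure under chemical-modification
#' constraints), `eval(sequence, pairs)` (free energy of a given structure,
#' no refolding) and `fold_energies(sequences)` (batch MFE energies, used by
#' the sliding-window scan). All energies are kcal/mol at 37 degrees C;
#' engines are deterministic for fixed inputs.
#'
#' Two engines are provided: [engine_builtin()], a self-contained
#' nearest-neighbor dynamic program that fully supports the
#' chemical-modification constraint semantics, and [engine_vienna()], an
#' adapter for the ViennaRNA `RNAfold`/`RNAeval` programs (full Turner
#' model; unconstrained folding and energy evaluation only).
#'
#' @name folding_engine
NULL

.base_codes <- c(A = 0L, C = 1L, G = 2L, U = 3L)

.seq_to_codes <- function(sequence) {
  sequence <- toupper(gsub("T", "U", sequence))
  chars <- strsplit(sequence, "")[[1]]
  codes <- .base_codes[chars]
  if (anyNA(codes))
    stop("sequence contains non-ACGU characters: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "))
  unname(codes)
}

#' Nearest-neighbor energy parameters of the built-in engine
#'
#' A compact stacking table (Watson-Crick and GU wobble doublets, values in
#' the spirit of the Turner nearest-neighbor sets), logarithmic
#' hairpin/bulge/internal-loop penalties and a linear multiloop model.
#' The table is symmetric under helix reversal:
#' `stack[p, q] == stack[rev(q), rev(p)]`.
#'
#' @return list of parameters consumed by [engine_builtin()].
#' @export
builtin_energy_params <- function() {
  pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
  rev_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  st <- matrix(NA_real_, 6, 6, dimnames = list(pt, pt))
  put <- function(outer, inner, e) {
    st[outer, inner] <<- e
    st[rev_pair(inner), rev_pair(outer)] <<- e
  }
  # Watson-Crick on Watson-Crick
  put("AU", "AU", -0.93); put("AU", "UA", -1.10)
  put("AU", "CG", -2.24); put("AU", "GC", -2.08)
  put("UA", "AU", -1.33); put("UA", "UA", -0.93)
  put("UA", "CG", -2.35); put("UA", "GC", -2.11)
  put("CG", "CG", -3.26); put("CG", "GC", -2.36)
  put("GC", "CG", -3.42); put("GC", "GC", -3.26)
  # one wobble neighbor
  put("AU", "GU", -0.55); put("AU", "UG", -1.36)
  put("UA", "GU", -1.00); put("UA", "UG", -0.55)
  put("CG", "GU", -1.41); put("CG", "UG", -2.11)
  put("GC", "GU", -1.53); put("GC", "UG", -2.51)
  # tandem wobble
  put("GU", "GU", -0.50); put("GU", "UG", -0.74)
  put("UG", "GU", +0.47)
  st["UG", "UG"] <- st["GU", "GU"]  # helix-reversal image of GU/GU
  stopifnot(!anyNA(st))
  list(stack = st,
       hairpin_a = 5.4, hairpin_b = 1.08,
       bulge_a = 3.8, bulge_b = 1.08,
       intl_a = 4.0, intl_b = 1.08,
       ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.1,
       max_loop = 30L, min_hairpin = 3L)
}

#' Built-in folding engine
#'
#' Zuker-style minimum free energy folding over nested structures with
#' canonical pairs (AU, UA, CG, GC, GU, UG) and a minimum hairpin loop of
#' 3 nt, using the embedded parameter table of [builtin_energy_params()].
#' Chemical-modification constraints are honored exactly: a flagged
#' position may not occupy a pair flanked on both sides by pairs
#' (helix-internal position); helix-terminal pairing and unpaired states
#' remain allowed.
#'
#' @param params parameter list, see [builtin_energy_params()].
#' @return a `folding_engine`.
#' @export
engine_builtin <- function(params = builtin_energy_params()) {
  eng <- list(
    name = "builtin",
    params = params,
    fold = function(sequence, modified = integer(0)) {
      codes <- .seq_to_codes(sequence)
      n <- length(codes)
      modified <- as.integer(modified)
      if (length(modified) && (min(modified) < 1L || max(modified) > n))
        stop("constraint position outside [1, ", n, "]")
      mask <- rep(FALSE, n)
      mask[modified] <- TRUE
      res <- .fold_mfe_cpp(codes, mask, params)
      list(pairs = data.frame(i = res$i, j = res$j), energy = res$energy)
    },
    eval = function(sequence, pairs) {
      codes <- .seq_to_codes(sequence)
      .eval_energy_cpp(codes, as.integer(pairs$i), as.integer(pairs$j), params)
    },
    fold_energies = function(sequences) {
      vapply(sequences, function(s) {
        codes <- .seq_to_codes(s)
        .fold_mfe_cpp(codes, rep(FALSE, length(codes)), params)$energy
      }, numeric(1), USE.NAMES = FALSE)
    })
  structure(eng, class = "folding_engine")
}

#' ViennaRNA folding engine adapter
#'
#' Wraps the external `RNAfold` and `RNAeval` programs (full Turner
#' nearest-neighbor model at 37 degrees C). Supports unconstrained MFE
#' folding, batch folding for window scans, and energy evaluation of given
#' structures. Chemical-modification constraints are not expressible in
#' RNAfold's constraint language, so constrained folds must use
#' [engine_builtin()]; requesting them here is an error.
#'
#' @param rnafold,rnaeval paths to the executables.
#' @return a `folding_engine`.
#' @export
engine_vienna <- function(rnafold = "RNAfold", rnaeval = "RNAeval") {
  if (Sys.which(rnafold) == "")
    stop("ViennaRNA adapter: executable not found: ", rnafold,
         " (configure the path or use engine_builtin())")
  run_fold <- function(seqs) {
    out <- system2(rnafold, c("--noPS"), input = seqs, stdout = TRUE)
    if (!is.null(attr(out, "status")))
      stop("RNAfold failed with status ", attr(out, "status"))
    out
  }
  parse_fold_line <- function(line) {
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)$", line))[[1]]
    if (!length(m)) stop("could not parse RNAfold output: ", line)
    list(db = m[2], energy = as.numeric(m[3]))
  }
  eng <- list(
    name = "vienna",
    fold = function(sequence, modified = integer(0)) {
      if (length(modified))
        stop("the ViennaRNA adapter does not support chemical-modification ",
             "constraints; use engine_builtin() for constrained folding")
      out <- run_fold(toupper(gsub("T", "U", sequence)))
      res <- parse_fold_line(out[2])
      list(pairs = dotbracket_to_pairs(res$db), energy = res$energy)
    },
    eval = function(sequence, pairs) {
      db <- pairs_to_dotbracket(pairs, nchar(sequence))
      out <- system2(rnaeval, character(0),
                     input = c(toupper(gsub("T", "U", sequence)), db),
                     stdout = TRUE)
      if (!is.null(attr(out, "status")))
        stop("RNAeval failed with status ", attr(out, "status"))
      last <- out[length(out)]
      m <- regmatches(last, regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", last))[[1]]
      if (!length(m)) stop("could not parse RNAeval output: ", last)
      as.numeric(m[2])
    },
    fold_energies = function(sequences) {
      out <- run_fold(toupper(gsub("T", "U", sequences)))
      vapply(seq_along(sequences), function(k)
        parse_fold_line(out[2 * k])$energy, numeric(1))
    })
  structure(eng, class = "folding_engine")
}

#' @export
print.folding_engine <- function(x, ...) {
  cat("Folding engine:", x$name, "(37 C, canonical pairs incl. GU)\n")
  invisible(x)
}
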