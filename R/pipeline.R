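#' Run the pipeline from a declarative configuration
#'
#' Executes the requested stages in order: simulate -> count -> reactivity
#' -> (scan | fold -> bootstrap -> conserve). Intermediate results are
#' written as TSV next to `out_dir`, and every run writes a metadata
#' record (`run_metadata.json`: parameters, seed, package version)
#' alongside the outputs so any output is regenerable from its metadata.
#'
#' Recognized configuration keys (flat list or YAML file):
#' `stages` (character vector; default `"all"`), `out_dir`, `seed`,
#' `fasta`, `sam_treated`, `sam_untreated`, `primers` (panel TSV),
#' `engine` (`"builtin"` or `"vienna"`), `window`, `step`, `shuffles`,
#' `strong`, `moderate`, `boot_n`, `boot_frac`, `min_rt`, `rt_window`
#' (e.g. `"100:380"`), `primer_excl`, `min_len`, `max_mm`, `fold_from`,
#' `fold_to`, `alignment` (aligned FASTA for conservation), and the
#' [sim_config()] fields under `sim_*` for the simulate stage.
#'
#' @param config a named list, or path to a YAML file.
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  get <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  stages <- get("stages", "all")
  all_stages <- c("simulate", "count", "reactivity", "scan", "fold",
                  "bootstrap", "conserve")
  if (identical(stages, "all")) {
    stages <- all_stages
    # conservation needs an external alignment; "all" without one runs the rest
    if (is.null(config$alignment)) stages <- setdiff(stages, "conserve")
  }
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- get("out_dir", ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(get("seed", 1L))
  engine <- switch(get("engine", "builtin"),
                   builtin = engine_builtin(), vienna = engine_vienna(),
                   stop("engine must be 'builtin' or 'vienna'"))
  rtw <- as.integer(strsplit(as.character(get("rt_window", "100:380")), ":")[[1]])
  res <- list()

  meta <- list(package = "tstructseq",
               version = as.character(utils::packageVersion("tstructseq")),
               seed = seed, stages = stages,
               parameters = config[setdiff(names(config), "stages")])
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  if ("simulate" %in% stages) {
    cfg <- sim_config(
      length = get("sim_length", 2000L),
      p_hit = get("sim_p_hit", 0.01), p_bg = get("sim_p_bg", 5e-4),
      p_spont = get("sim_p_spont", 2e-3),
      dose_scale = get("sim_dose_scale", 1),
      reads_per_primer = get("sim_reads_per_primer", 10000L),
      seed = seed)
    tx <- make_transcript(cfg)
    rt <- simulate_reads(tx, cfg, "treated")
    ru <- simulate_reads(tx, cfg, "untreated")
    fa <- file.path(out_dir, "sim_transcript.fa")
    writeLines(c(paste0(">", tx$transcript$name), tx$transcript$sequence), fa)
    write_sam(rt, tx$transcript, file.path(out_dir, "sim_treated.sam"))
    write_sam(ru, tx$transcript, file.path(out_dir, "sim_untreated.sam"))
    utils::write.table(tx$truth, file.path(out_dir, "sim_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(tx$panel),
                       file.path(out_dir, "sim_primers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    config$fasta <- fa
    config$sam_treated <- file.path(out_dir, "sim_treated.sam")
    config$sam_untreated <- file.path(out_dir, "sim_untreated.sam")
    config$primers <- file.path(out_dir, "sim_primers.tsv")
    res$simulate <- tx
  }

  tx_ref <- NULL
  if (!is.null(config$fasta)) tx_ref <- load_transcript(config$fasta)

  if ("count" %in% stages || "reactivity" %in% stages) {
    if (is.null(tx_ref)) stop("count stage needs 'fasta'")
    panel <- read_primer_panel(config$primers, tx_ref)
    load_counts <- function(sam, condition) {
      reads <- read_alignments(sam, tx_ref)
      if (!nrow(reads)) warning("no aligned reads in ", sam)
      reads <- filter_alignments(reads,
                                 min_len = get("min_len", 60L),
                                 max_mismatch = get("max_mm", 2L))
      count_terminations(reads, panel, condition, tx_ref$length,
                         primer_exclusion = get("primer_excl", 25L))
    }
    ct <- load_counts(config$sam_treated, "treated")
    cu <- load_counts(config$sam_untreated, "untreated")
    write_counts_tsv(c(ct, cu), tx_ref$name, file.path(out_dir, "counts.tsv"))
    res$count <- list(treated = ct, untreated = cu)
    if ("reactivity" %in% stages) {
      profiles <- lapply(names(ct), function(p) compute_pdms(ct[[p]], cu[[p]]))
      combined <- combine_primers(profiles,
                                  window = rtw,
                                  min_readthrough = get("min_rt", 1000))
      combined <- classify_reactivity(combined,
                                      strong = get("strong", 0.008),
                                      moderate = get("moderate", 0.004))
      write_reactivity_tsv(combined, tx_ref,
                           file.path(out_dir, "reactivity.tsv"))
      res$reactivity <- combined
    }
  }

  if ("scan" %in% stages) {
    if (is.null(tx_ref)) stop("scan stage needs 'fasta'")
    scores <- zscore_scan(tx_ref$sequence, engine,
                          window = get("window", 150L),
                          step = get("step", 10L),
                          n_shuffles = get("shuffles", 25L), seed = seed)
    regions <- call_regions(scores, cutoff = get("cutoff", "auto"),
                            gap_join = get("gap_join", 0L))
    write_windows_tsv(scores, file.path(out_dir, "windows.tsv"))
    write_regions_tsv(regions, file.path(out_dir, "regions.tsv"))
    res$scan <- list(scores = scores, regions = regions)
  }

  if (any(c("fold", "bootstrap") %in% stages)) {
    if (is.null(tx_ref)) stop("fold stage needs 'fasta'")
    from <- get("fold_from", 1L); to <- get("fold_to", tx_ref$length)
    frag <- substr(tx_ref$sequence, from, to)
    cons <- integer(0)
    if (!is.null(res$reactivity)) {
      cons <- make_constraints(subset_profile(res$reactivity, from, to),
                               threshold = get("strong", 0.008))
    }
    st <- mfe_fold(frag, cons, engine,
                   name = sprintf("%s_%d_%d", tx_ref$name, from, to))
    write_ct(frag, st, file.path(out_dir, "model.ct"))
    write_dotbracket(frag, st, file.path(out_dir, "model.db"))
    write_constraints(cons, file.path(out_dir, "constraints.txt"))
    res$fold <- st
    if ("bootstrap" %in% stages) {
      bs <- bootstrap_support(frag, cons, engine,
                              n = get("boot_n", 1000L),
                              fraction = get("boot_frac", 0.5), seed = seed)
      utils::write.table(as.data.frame(bs),
                         file.path(out_dir, "bootstrap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$bootstrap <- bs
    }
  }

  if ("conserve" %in% stages) {
    if (is.null(res$fold)) stop("conserve stage needs a folded model")
    if (is.null(config$alignment)) stop("conserve stage needs 'alignment'")
    aln <- read_alignment(config$alignment, reference = config$reference)
    rep <- conservation_report(res$fold, aln)
    write_conservation_tsv(rep, file.path(out_dir, "conservation.tsv"))
    utils::write.table(attr(rep, "summary"),
                       file.path(out_dir, "conservation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$conserve <- rep
  }
  invisible(res)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/tstructseq` Rscript:
#' `tstructseq <subcommand> --config run.yaml [--out-dir DIR] [--seed N]`.
#' Subcommands map onto pipeline stages (`simulate`, `count`,
#' `reactivity`, `scan`, `fold`, `bootstrap`, `conserve`, `all`).
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: tstructseq <simulate|count|reactivity|scan|fold|bootstrap|conserve|all> --config FILE [--out-dir DIR] [--seed N]"
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  stage <- args[1]
  known_stages <- c("simulate", "count", "reactivity", "scan", "fold",
                    "bootstrap", "conserve", "all")
  if (!stage %in% known_stages) {
    message("unknown subcommand: ", stage, "\n", usage)
    return(invisible(2L))
  }
  opt <- list(config = NULL, out_dir = NULL, seed = NULL)
  k <- 2L
  while (k <= length(args)) {
    key <- sub("^--", "", args[k])
    key <- gsub("-", "_", key)
    if (!key %in% names(opt) || k == length(args)) {
      message("unknown or incomplete option: ", args[k], "\n", usage)
      return(invisible(2L))
    }
    opt[[key]] <- args[k + 1L]
    k <- k + 2L
  }
  config <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
  stage_sets <- list(
    simulate = "simulate", count = "count",
    reactivity = c("count", "reactivity"), scan = "scan", fold = "fold",
    bootstrap = c("fold", "bootstrap"), conserve = c("fold", "conserve"),
    all = "all")
  config$stages <- stage_sets[[stage]]
  if (!is.null(opt$out_dir)) config$out_dir <- opt$out_dir
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  status <- tryCatch({
    run_pipeline(config)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
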