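# End-to-end orchestration: simulate -> call -> subtract -> annotate ->
# rank -> (optionally) map onto a structure, from one structured config.

default_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    screen = list(
      n_genes = 20L, gene_length_bp = 999L, intergenic_bp = 100L,
      n_clones = 10L, n_resistant = 8L, shared_multiplicity = 2L,
      causal_gene = "g001", per_base_rate = 1e-5,
      spectrum = "enu", proportions = "equal", dirichlet_alpha = NULL,
      mean_depth = 150, seq_error = 0.001, fwd_fraction = 0.5
    ),
    caller = list(
      min_depth = 50L, maf_low = 0.03, maf_standard = 0.07,
      lrt_alpha = 1e-6, strand_alpha = 0.01, error_floor = 1e-6,
      maf_ceiling = 0.01, fwd_fraction = 0.5
    ),
    annotation = list(splice_window = 2L),
    ranking = list(min_recurrence = 2L, mode = "low"),
    structure = list(pdb = NULL, ligand = NULL, chain = NULL,
                     offset = 0L, d1 = 5, d2 = 8, substitutions = NULL)
  )
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in '%s': %s", block,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  modifyList(defaults, user, keep.null = TRUE)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a nested list), fills in defaults,
#' rejects unknown keys, and checks cross-parameter invariants.
#'
#' @param config Path to a YAML config file, or a nested list, or
#'   `NULL` for all defaults.
#' @return A fully defaulted config list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  defs <- default_config()
  config <- config %||% list()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defs
  cfg$seed <- as.integer(config$seed %||% defs$seed)
  cfg$outdir <- config$outdir %||% defs$outdir
  for (block in c("screen", "caller", "annotation", "ranking", "structure")) {
    cfg[[block]] <- merge_block(defs[[block]], config[[block]], block)
  }
  s <- cfg$screen
  if (s$n_resistant > s$n_clones) {
    stop("screen: n_resistant must be <= n_clones", call. = FALSE)
  }
  if (!s$spectrum %in% c("enu", "uniform")) {
    stop("screen: spectrum must be 'enu' or 'uniform'", call. = FALSE)
  }
  # caller invariants enforced by the constructor
  do.call(caller_params, cfg$caller)
  if (!cfg$ranking$mode %in% c("low", "standard")) {
    stop("ranking: mode must be 'low' or 'standard'", call. = FALSE)
  }
  if (!is.null(cfg$structure$pdb) && is.null(cfg$structure$ligand)) {
    stop("structure: ligand name required when a pdb file is given",
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full suppressor-screen pipeline
#'
#' Simulates a selected and an unselected control pool, writes counts
#' tables and truth, calls variants in both, subtracts the control,
#' annotates and filters consequences, ranks candidate genes, and (when
#' structure inputs are configured) maps candidate substitutions onto
#' the protein-ligand complex. All artifacts and a parameter/stage log
#' land in the output directory.
#'
#' @param config A [validate_config()] object, a YAML path, a nested
#'   list, or `NULL` for defaults.
#' @param outdir Output directory (overrides the config; defaults to a
#'   fresh directory under `tempdir()`).
#' @return A list of class `pipeline_result`: `status` (0 = causal
#'   gene recovered at rank 1, 3 = truth known but not recovered),
#'   `outdir`, `report`, `calls`, `truth`, `error_rate`, and
#'   `interface` when a structure was mapped.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else {
    validate_config(config)
  }
  outdir <- outdir %||% cfg$outdir %||%
    file.path(tempdir(), sprintf("haploscreen-run-%d", cfg$seed))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file(file.path(outdir, "pipeline.log"), "w")
  on.exit(close(log))
  log_line(log, "haploscreen pipeline; seed=%d", cfg$seed)
  log_line(log, "config: %s",
           gsub("\n", " ", yaml::as.yaml(unclass(cfg)), fixed = TRUE))

  s <- cfg$screen
  spectrum <- if (s$spectrum == "uniform") uniform_spectrum() else enu_spectrum()
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  genome <- make_toy_genome(s$n_genes, s$gene_length_bp, s$intergenic_bp,
                            seed = stage_seeds[[1L]])
  models <- gene_models(genome)
  write_genome_files(genome, file.path(outdir, "genome.fa"),
                     file.path(outdir, "genes.gff3"))
  log_line(log, "genome: %d genes, %d bp", s$n_genes,
           sum(nchar(genome$contigs)))

  treated <- build_screen(genome, s$n_clones, s$causal_gene, s$n_resistant,
                          s$per_base_rate, spectrum,
                          proportions = s$proportions,
                          shared_multiplicity = s$shared_multiplicity,
                          dirichlet_alpha = s$dirichlet_alpha,
                          seed = stage_seeds[[2L]])
  control <- build_screen(genome, s$n_clones, s$causal_gene,
                          n_resistant = 0L, s$per_base_rate, spectrum,
                          seed = stage_seeds[[3L]])
  write_truth(treated$truth, file.path(outdir, "truth_treated.yaml"))
  write_truth(control$truth, file.path(outdir, "truth_control.yaml"))
  log_line(log, "screen: %d clones (%d resistant), %d causal SNV record(s)",
           s$n_clones, s$n_resistant, nrow(treated$truth$causal_snvs))

  set.seed(stage_seeds[[4L]])
  counts_t <- sample_pool_counts(treated$clones, genome,
                                 proportions = treated$truth$proportions,
                                 mean_depth = s$mean_depth,
                                 seq_error = s$seq_error,
                                 fwd_fraction = s$fwd_fraction,
                                 all_sites = TRUE)
  counts_c <- sample_pool_counts(control$clones, genome,
                                 proportions = control$truth$proportions,
                                 mean_depth = s$mean_depth,
                                 seq_error = s$seq_error,
                                 fwd_fraction = s$fwd_fraction,
                                 all_sites = TRUE)
  write_counts_tsv(counts_t, file.path(outdir, "counts_treated.tsv"))
  write_counts_tsv(counts_c, file.path(outdir, "counts_control.tsv"))
  log_line(log, "counts: %d treated / %d control site records",
           nrow(counts_t), nrow(counts_c))

  params <- do.call(caller_params, cfg$caller)
  calls_t <- call_variants(counts_t, params)
  calls_c <- call_variants(counts_c, params)
  write_calls_vcf(calls_t, file.path(outdir, "calls_treated_raw.vcf"))
  log_line(log, "caller: global error %.3g; %d treated / %d control calls",
           attr(calls_t, "global_error"), nrow(calls_t), nrow(calls_c))

  sub <- subtract_control(calls_t, calls_c)
  log_line(log, "control subtraction: %d removed, %d kept",
           nrow(sub$removed), nrow(sub$calls))

  ann <- annotate_variants(sub$calls, models,
                           splice_window = cfg$annotation$splice_window)
  kept <- filter_effect(ann)
  write_calls_vcf(ann, file.path(outdir, "calls_annotated.vcf"))
  log_line(log, "annotation: %d calls, %d moderate/high", nrow(ann),
           nrow(kept))

  ranked <- rank_genes(kept, models,
                       min_recurrence = cfg$ranking$min_recurrence,
                       mode = cfg$ranking$mode, n_clones = s$n_clones)
  report <- screen_report(ranked, treated$truth)
  write_report_tsv(report, file.path(outdir, "candidates.tsv"))
  log_line(log, "ranking: %d candidate gene(s); causal %s rank %s",
           nrow(ranked), report$causal_gene %||% "-",
           ifelse(is.na(report$causal_rank %||% NA), "-",
                  report$causal_rank))

  result <- list(outdir = outdir, report = report, calls = kept,
                 truth = treated$truth,
                 error_rate = attr(calls_t, "global_error"))

  st <- cfg$structure
  if (!is.null(st$pdb)) {
    cx <- read_structure(st$pdb, st$ligand, st$chain)
    subs <- st$substitutions %||% {
      v <- report$variants
      unique(v$substitution[!is.na(v$substitution)])
    }
    result$interface <- classify_substitutions(
      subs, cx, residue_map(offset = st$offset, chain = st$chain),
      d1 = st$d1, d2 = st$d2
    )
    write.table(result$interface, file.path(outdir, "interface.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(log, "structure: %d substitution(s) classified",
             nrow(result$interface))
  }

  # 0 = causal gene recovered at rank 1; 3 = truth known, not recovered
  result$status <- if (isTRUE(report$recovered)) 0L else 3L
  log_line(log, "status: %d", result$status)
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: status %d; artifacts in %s\n",
              x$status, x$outdir))
  print(x$report)
  invisible(x)
}
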