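# Candidate-gene ranking: recurrence of distinct protein-altering
# alleles per gene, normalized by coding-sequence size in kbp.

#' Estimate clone multiplicity from a pooled MAF
#'
#' In an N-clone pool each carrier clone contributes ~1/N of allele
#' frequency, so the number of clones carrying a variant is estimated
#' as round(maf * N), at least 1. A MAF of 22.6% in a 10-clone pool
#' implies 2 carrier clones.
#'
#' @param maf Pooled mutant allele fraction(s) in (0, 1].
#' @param n_clones Clones in the pool.
#' @return Integer estimate(s) of carrier clones.
#' @examples
#' estimate_clone_multiplicity(0.226, 10)  # 2
#' @export
estimate_clone_multiplicity <- function(maf, n_clones) {
  if (any(maf <= 0) || any(maf > 1)) {
    stop("maf must lie in (0, 1]", call. = FALSE)
  }
  pmax(1L, as.integer(round(maf * n_clones)))
}

#' Rank candidate genes by protein-altering hits per kbp
#'
#' Aggregates annotated, protein-function-affecting calls per gene,
#' counting distinct variant alleles (position + alternate base; a
#' shared allele appears once at higher MAF and is still one hit),
#' requires at least `min_recurrence` hits, and sorts by hits per kbp
#' of coding sequence (descending), breaking ties by raw hit count
#' then gene id.
#'
#' @param calls Annotated calls (from [annotate_variants()] /
#'   [filter_effect()]) with `passes_low` / `passes_standard` flags.
#' @param models A `gene_model_set` providing CDS lengths.
#' @param min_recurrence Minimum distinct qualifying alleles per gene
#'   (default 2).
#' @param mode `"low"` (>= 3% MAF gate) or `"standard"` (>= 7%).
#' @param n_clones If given, the per-variant table in attribute
#'   `"variants"` gains clone-multiplicity estimates.
#' @return A data.frame of class `candidate_table`: `gene_id`,
#'   `n_hits`, `cds_kbp`, `hits_per_kbp`, `rank`; per-variant details
#'   in `attr(, "variants")`.
#' @export
rank_genes <- function(calls, models, min_recurrence = 2L,
                       mode = c("low", "standard"), n_clones = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(models, "gene_model_set"))
  if (!all(c("gene_id", "impact") %in% names(calls))) {
    stop("calls must be annotated (gene_id/impact columns)", call. = FALSE)
  }
  flag <- if (mode == "low") "passes_low" else "passes_standard"
  qual <- calls[!is.na(calls$gene_id) &
                  calls$impact %in% c("moderate", "high") &
                  calls[[flag]], , drop = FALSE]
  # distinct alleles
  qual <- qual[!duplicated(paste(qual$gene_id, qual$contig, qual$pos,
                                 qual$alt, sep = ":")), , drop = FALSE]
  if (!is.null(n_clones) && nrow(qual)) {
    qual$est_clones <- estimate_clone_multiplicity(pmax(qual$maf, 1e-12),
                                                   n_clones)
  }
  lens <- cds_lengths(models)
  tab <- if (nrow(qual)) {
    counts <- table(qual$gene_id)
    data.frame(gene_id = names(counts), n_hits = as.integer(counts),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), n_hits = integer(),
               stringsAsFactors = FALSE)
  }
  tab <- tab[tab$n_hits >= min_recurrence, , drop = FALSE]
  if (nrow(tab)) {
    unknown <- setdiff(tab$gene_id, names(lens))
    if (length(unknown)) {
      stop("no gene model for: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    tab$cds_kbp <- lens[tab$gene_id] / 1000
    tab$hits_per_kbp <- tab$n_hits / tab$cds_kbp
    tab <- tab[order(-tab$hits_per_kbp, -tab$n_hits, tab$gene_id), ,
               drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
  } else {
    tab <- data.frame(gene_id = character(), n_hits = integer(),
                      cds_kbp = numeric(), hits_per_kbp = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  structure(tab, class = c("candidate_table", "data.frame"),
            variants = qual, mode = mode,
            min_recurrence = as.integer(min_recurrence))
}

#' Summarize a screen, optionally against ground truth
#'
#' Produces the screen's output table (gene, hits, hits/kbp) and, when
#' simulation truth is supplied, whether the causal gene was recovered
#' as the top-ranked candidate.
#'
#' @param ranked A [rank_genes()] result.
#' @param truth Optional `screen_truth`.
#' @return A list of class `screen_report`: `candidates`, `variants`,
#'   and (with truth) `causal_gene`, `causal_rank`, `recovered`.
#' @export
screen_report <- function(ranked, truth = NULL) {
  stopifnot(inherits(ranked, "candidate_table"))
  rep <- list(candidates = as.data.frame(ranked),
              variants = attr(ranked, "variants"),
              mode = attr(ranked, "mode"))
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "screen_truth"))
    rep$causal_gene <- truth$causal_gene
    idx <- match(truth$causal_gene, ranked$gene_id)
    rep$causal_rank <- if (is.na(idx)) NA_integer_ else ranked$rank[[idx]]
    rep$recovered <- !is.na(idx) && ranked$rank[[idx]] == 1L
  }
  structure(rep, class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Candidate genes (%s stringency, recurrent protein-altering hits):\n",
              x$mode))
  if (nrow(x$candidates)) {
    print(x$candidates, row.names = FALSE)
  } else {
    cat("  (none)\n")
  }
  if (!is.null(x$recovered)) {
    cat(sprintf("Causal gene %s: %s (rank %s)\n", x$causal_gene,
                if (x$recovered) "recovered at rank 1" else "not recovered",
                ifelse(is.na(x$causal_rank), "-", x$causal_rank)))
  }
  invisible(x)
}

#' Write a candidate report as TSV
#'
#' @param report A [screen_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  write.table(report$candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
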