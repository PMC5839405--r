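# Gene models and coding-consequence annotation.
#
# A gene model is a single-transcript CDS: an ordered set of 1-based
# closed intervals on one strand whose spliced length is a multiple of
# 3. Consequences are classified at codon level with the standard
# genetic code; the 2 intronic bases flanking each internal CDS
# boundary are treated as splice sites (canonical donor/acceptor).

IMPACT_RANK <- c(none = 0L, low = 1L, moderate = 2L, high = 3L)

new_gene_model_set <- function(cds, contigs) {
  stopifnot(is.data.frame(cds), is.character(contigs), !is.null(names(contigs)))
  needed <- c("gene_id", "contig", "strand", "start", "end")
  if (!all(needed %in% names(cds))) {
    stop("cds table needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  genes <- list()
  for (gid in unique(cds$gene_id)) {
    rows <- cds[cds$gene_id == gid, , drop = FALSE]
    contig <- rows$contig[[1L]]
    strand <- rows$strand[[1L]]
    if (!contig %in% names(contigs)) {
      stop(sprintf("gene %s: contig %s not in sequence set", gid, contig),
           call. = FALSE)
    }
    if (!strand %in% c("+", "-")) {
      stop(sprintf("gene %s: strand must be '+' or '-'", gid), call. = FALSE)
    }
    rows <- rows[order(rows$start), , drop = FALSE]
    if (any(rows$start > rows$end)) {
      stop(sprintf("gene %s: interval start > end", gid), call. = FALSE)
    }
    if (nrow(rows) > 1L && any(rows$start[-1L] <= rows$end[-nrow(rows)])) {
      stop(sprintf("gene %s: CDS intervals overlap", gid), call. = FALSE)
    }
    clen <- nchar(contigs[[contig]])
    if (rows$start[[1L]] < 1L || rows$end[[nrow(rows)]] > clen) {
      stop(sprintf("gene %s: CDS outside contig bounds", gid), call. = FALSE)
    }
    cds_length <- sum(rows$end - rows$start + 1L)
    if (cds_length %% 3L != 0L) {
      stop(sprintf("gene %s: CDS length %d is not a multiple of 3",
                   gid, cds_length), call. = FALSE)
    }
    pieces <- substring(contigs[[contig]], rows$start, rows$end)
    cds_seq <- paste0(pieces, collapse = "")
    if (strand == "-") cds_seq <- revcomp(cds_seq)
    genes[[gid]] <- list(
      gene_id = gid, contig = contig, strand = strand,
      cds = rows[, c("start", "end")], cds_length = cds_length,
      cds_seq = cds_seq,
      span = c(rows$start[[1L]], rows$end[[nrow(rows)]])
    )
  }
  structure(list(genes = genes, contigs = contigs), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d gene(s) on %d contig(s)\n",
              length(x$genes), length(x$contigs)))
  invisible(x)
}

#' Gene models of a toy genome
#'
#' @param genome A [make_toy_genome()] object.
#' @return A `gene_model_set` usable by [annotate_variants()].
#' @export
gene_models <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  new_gene_model_set(genome$cds, genome$contigs)
}

#' CDS lengths of a model set
#'
#' @param models A `gene_model_set`.
#' @return Named integer vector of CDS lengths in bp.
#' @export
cds_lengths <- function(models) {
  stopifnot(inherits(models, "gene_model_set"))
  vapply(models$genes, function(g) as.integer(g$cds_length), integer(1L))
}

#' Load gene models from GFF3 and FASTA files
#'
#' Reads CDS features (grouped by gene through their mRNA parents, or
#' directly by a gene parent) and the contig sequences, and validates
#' the usual single-transcript CDS invariants. Minus-strand models use
#' the reverse complement of the genomic span.
#'
#' @param gff3_file Path to a GFF3 file with gene/mRNA/CDS features.
#' @param fasta_file Path to a FASTA file with the contig sequences.
#' @return A `gene_model_set`.
#' @export
load_gene_models <- function(gff3_file, fasta_file) {
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  contigs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  gr <- rtracklayer::import(gff3_file, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parent_of <- function(i) {
    p <- meta$Parent[[i]]
    if (length(p)) as.character(p)[[1L]] else NA_character_
  }
  # map feature id -> owning gene id (follow Parent links one level up)
  gene_of <- setNames(ids[type == "gene"], ids[type == "gene"])
  for (i in which(type %in% c("mRNA", "transcript"))) {
    p <- parent_of(i)
    gene_of[[ids[[i]]]] <- if (!is.na(p) && p %in% names(gene_of)) gene_of[[p]] else p %||% ids[[i]]
  }
  keep <- which(type == "CDS")
  if (!length(keep)) stop("no CDS features found in GFF3", call. = FALSE)
  gene_id <- vapply(keep, function(i) {
    p <- parent_of(i)
    if (!is.na(p) && p %in% names(gene_of)) gene_of[[p]] else p %||% "unknown"
  }, character(1L))
  cds <- data.frame(
    gene_id = gene_id,
    contig = as.character(GenomicRanges::seqnames(gr)[keep]),
    strand = as.character(GenomicRanges::strand(gr)[keep]),
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    stringsAsFactors = FALSE
  )
  new_gene_model_set(cds, contigs)
}

# genomic position -> 1-based position in the spliced coding sequence
cds_coordinate <- function(gene, pos) {
  rows <- gene$cds
  offsets <- cumsum(c(0L, rows$end - rows$start + 1L))
  if (gene$strand == "+") {
    for (j in seq_len(nrow(rows))) {
      if (pos >= rows$start[[j]] && pos <= rows$end[[j]]) {
        return(offsets[[j]] + (pos - rows$start[[j]] + 1L))
      }
    }
  } else {
    ord <- rev(seq_len(nrow(rows)))  # transcription order for minus strand
    offsets <- cumsum(c(0L, (rows$end - rows$start + 1L)[ord]))
    for (k in seq_along(ord)) {
      j <- ord[[k]]
      if (pos >= rows$start[[j]] && pos <= rows$end[[j]]) {
        return(offsets[[k]] + (rows$end[[j]] - pos + 1L))
      }
    }
  }
  NA_integer_
}

annotate_one <- function(contig, pos, ref, alt, models, splice_window = 2L) {
  res <- data.frame(
    gene_id = NA_character_, category = "intergenic", impact = "none",
    ref_aa = NA_character_, alt_aa = NA_character_,
    protein_pos = NA_integer_, stringsAsFactors = FALSE
  )
  obs <- genome_base(models, contig, pos)
  if (nzchar(obs) && obs != ref) {
    stop(sprintf("ref mismatch at %s:%d: expected %s, genome has %s",
                 contig, pos, ref, obs), call. = FALSE)
  }
  best <- res
  for (gene in models$genes) {
    if (gene$contig != contig) next
    if (pos < gene$span[[1L]] || pos > gene$span[[2L]]) next
    cpos <- cds_coordinate(gene, pos)
    if (!is.na(cpos)) {
      tx_ref <- if (gene$strand == "-") complement_base(ref) else ref
      tx_alt <- if (gene$strand == "-") complement_base(alt) else alt
      codon_i <- (cpos - 1L) %/% 3L
      within <- (cpos - 1L) %% 3L
      codon <- substring(gene$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      stopifnot(substring(codon, within + 1L, within + 1L) == tx_ref)
      new_codon <- codon
      substring(new_codon, within + 1L, within + 1L) <- tx_alt
      ref_aa <- translate_codon(codon)
      alt_aa <- translate_codon(new_codon)
      cand <- if (ref_aa == alt_aa) {
        c("synonymous", "low")
      } else if (alt_aa == "*") {
        c("stop_gained", "high")
      } else if (ref_aa == "*") {
        c("stop_lost", "high")
      } else {
        c("missense", "moderate")
      }
      row <- data.frame(
        gene_id = gene$gene_id, category = cand[[1L]], impact = cand[[2L]],
        ref_aa = ref_aa, alt_aa = alt_aa, protein_pos = codon_i + 1L,
        stringsAsFactors = FALSE
      )
    } else {
      # intronic side: splice site if within splice_window of a CDS edge
      rows <- gene$cds
      near_edge <- FALSE
      if (nrow(rows) > 1L) {
        for (j in seq_len(nrow(rows) - 1L)) {
          intron_start <- rows$end[[j]] + 1L
          intron_end <- rows$start[[j + 1L]] - 1L
          if (pos >= intron_start && pos <= intron_end &&
              (pos - intron_start < splice_window ||
               intron_end - pos < splice_window)) {
            near_edge <- TRUE
            break
          }
        }
      }
      row <- data.frame(
        gene_id = gene$gene_id,
        category = if (near_edge) "splice_site" else "intronic",
        impact = if (near_edge) "high" else "none",
        ref_aa = NA_character_, alt_aa = NA_character_,
        protein_pos = NA_integer_, stringsAsFactors = FALSE
      )
    }
    if (IMPACT_RANK[[row$impact]] > IMPACT_RANK[[best$impact]] ||
        (is.na(best$gene_id) && !is.na(row$gene_id))) {
      best <- row
    }
  }
  best
}

#' Annotate coding consequences of SNVs
#'
#' Classifies each variant as synonymous, missense, stop_gained,
#' stop_lost, splice_site, intronic or intergenic against a set of gene
#' models, with impact low/moderate/high/none. Overlapping genes are
#' resolved by reporting the most severe consequence.
#'
#' @param variants A data.frame with columns `contig`, `pos`, `ref`,
#'   `alt` (e.g. an [snv_table()] or [call_variants()] output).
#' @param models A `gene_model_set`.
#' @param splice_window Intronic bases at each internal CDS boundary
#'   classified as splice site (default 2, the canonical donor/acceptor
#'   dinucleotide).
#' @return `variants` with appended columns `gene_id`, `category`,
#'   `impact`, `ref_aa`, `alt_aa`, `protein_pos`, `substitution`.
#' @export
annotate_variants <- function(variants, models, splice_window = 2L) {
  stopifnot(inherits(models, "gene_model_set"))
  n <- nrow(variants)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- annotate_one(variants$contig[[i]], variants$pos[[i]],
                             variants$ref[[i]], variants$alt[[i]],
                             models, splice_window)
  }
  ann <- if (n) do.call(rbind, out) else data.frame(
    gene_id = character(), category = character(), impact = character(),
    ref_aa = character(), alt_aa = character(), protein_pos = integer(),
    stringsAsFactors = FALSE
  )
  res <- cbind(variants, ann)
  res$substitution <- ifelse(
    res$category %in% c("missense", "stop_gained", "stop_lost"),
    paste0(res$ref_aa, res$protein_pos, res$alt_aa), NA_character_
  )
  rownames(res) <- NULL
  res
}

#' Keep protein-function-affecting consequences
#'
#' Retains variants with moderate or high impact (missense, stop gain
#' or loss, splice site), the classes counted towards candidate-gene
#' recurrence.
#'
#' @param consequences Output of [annotate_variants()].
#' @return The subset with `impact` in moderate/high.
#' @export
filter_effect <- function(consequences) {
  stopifnot("impact" %in% names(consequences))
  out <- consequences[consequences$impact %in% c("moderate", "high"), ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format an amino-acid substitution
#'
#' One-letter `<ref><position><alt>` notation (e.g. `"F256L"`); stop
#' codons are written `*` (e.g. `"W10*"`).
#'
#' @param consequences One or more rows of [annotate_variants()] output,
#'   all missense or stop_gained/stop_lost.
#' @return Character vector of substitution strings.
#' @export
format_substitution <- function(consequences) {
  ok <- consequences$category %in% c("missense", "stop_gained", "stop_lost")
  if (any(!ok)) {
    stop("format_substitution requires protein-altering consequences",
         call. = FALSE)
  }
  paste0(consequences$ref_aa, consequences$protein_pos, consequences$alt_aa)
}
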