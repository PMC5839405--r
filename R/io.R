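# On-disk formats: counts TSV, truth YAML, FASTA/GFF3 gene models,
# and a minimal VCF v4.2 writer for calls.

COUNTS_COLS <- c("contig", "pos", "ref", "alt", "depth", "alt_fwd", "alt_rev")

#' Read and write pooled counts tables
#'
#' Tab-separated, `#`-prefixed header, 1-based positions, columns
#' `contig, pos, ref, alt, depth, alt_fwd, alt_rev`.
#'
#' @param counts A counts data.frame.
#' @param path File path.
#' @return `read_counts_tsv()` returns the validated counts data.frame;
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  missing <- setdiff(COUNTS_COLS, names(counts))
  if (length(missing)) {
    stop("counts table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_counts(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(COUNTS_COLS, collapse = "\t")), con)
  if (nrow(counts)) {
    write.table(counts[, COUNTS_COLS], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(sub("^#", "", header),
                 paste(COUNTS_COLS, collapse = "\t"))) {
    stop("unrecognized counts header in ", path, call. = FALSE)
  }
  df <- read.table(path, sep = "\t", skip = 1L, col.names = COUNTS_COLS,
                   colClasses = c("character", "integer", "character",
                                  "character", "integer", "integer",
                                  "integer"))
  if (nrow(df) == 0L) {
    df <- data.frame(contig = character(), pos = integer(),
                     ref = character(), alt = character(),
                     depth = integer(), alt_fwd = integer(),
                     alt_rev = integer(), stringsAsFactors = FALSE)
  }
  validate_counts(df)
  df
}

validate_counts <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (any(df$pos < 1L)) {
    stop("counts positions are 1-based; found pos < 1", call. = FALSE)
  }
  if (any(df$depth < 0L) || any(df$alt_fwd < 0L) || any(df$alt_rev < 0L)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(df$alt_fwd + df$alt_rev > df$depth)) {
    stop("alt_fwd + alt_rev exceeds depth at some sites", call. = FALSE)
  }
  invisible(df)
}

#' Read and write screen ground truth
#'
#' Structured-text (YAML) round trip of a `screen_truth` object.
#'
#' @param truth A `screen_truth` from [build_screen()].
#' @param path File path.
#' @return `read_truth()` returns the `screen_truth`;
#'   `write_truth()` returns `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "screen_truth"))
  yaml::write_yaml(list(
    causal_gene = truth$causal_gene,
    proportions = as.list(truth$proportions),
    causal_snvs = lapply(seq_len(nrow(truth$causal_snvs)), function(i) {
      as.list(truth$causal_snvs[i, , drop = FALSE])
    }),
    background = lapply(seq_len(nrow(truth$background)), function(i) {
      as.list(truth$background[i, , drop = FALSE])
    })
  ), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  y <- yaml::read_yaml(path)
  rebuild <- function(rows) {
    if (!length(rows)) {
      return(cbind(data.frame(clone_id = character()), snv_table()))
    }
    df <- do.call(rbind, lapply(rows, as.data.frame,
                                stringsAsFactors = FALSE))
    df$pos <- as.integer(df$pos)
    rownames(df) <- NULL
    df
  }
  structure(list(
    causal_gene = y$causal_gene %||% NA_character_,
    causal_snvs = rebuild(y$causal_snvs),
    proportions = unlist(y$proportions),
    background = rebuild(y$background)
  ), class = "screen_truth")
}

#' Write a toy genome as FASTA and GFF3
#'
#' Contigs go to FASTA; gene models go to GFF3 as gene/mRNA/CDS
#' features (1-based closed intervals), round-trippable through
#' [load_gene_models()].
#'
#' @param genome A [make_toy_genome()] object.
#' @param fasta_file,gff3_file Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_genome_files <- function(genome, fasta_file, gff3_file) {
  stopifnot(inherits(genome, "toy_genome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), fasta_file
  )
  feats <- list()
  for (gid in unique(genome$cds$gene_id)) {
    rows <- genome$cds[genome$cds$gene_id == gid, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    span <- c(min(rows$start), max(rows$end))
    mrna_id <- paste0(gid, ".t1")
    feats[[length(feats) + 1L]] <- data.frame(
      contig = rows$contig[[1L]], start = span[[1L]], end = span[[2L]],
      strand = rows$strand[[1L]], type = c("gene", "mRNA"),
      ID = c(gid, mrna_id), Parent = c(NA, gid), phase = NA_integer_,
      stringsAsFactors = FALSE
    )
    lens <- rows$end - rows$start + 1L
    tx_order <- if (rows$strand[[1L]] == "-") rev(seq_along(lens)) else {
      seq_along(lens)
    }
    phase <- integer(length(lens))
    phase[tx_order] <- (3L - cumsum(c(0L, lens[tx_order]))[seq_along(lens)] %% 3L) %% 3L
    feats[[length(feats) + 1L]] <- data.frame(
      contig = rows$contig, start = rows$start, end = rows$end,
      strand = rows$strand, type = "CDS",
      ID = paste0(mrna_id, ".cds", seq_len(nrow(rows))), Parent = mrna_id,
      phase = phase, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$contig,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand
  )
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  S4Vectors::mcols(gr)$phase <- tab$phase
  rtracklayer::export(gr, gff3_file, format = "gff3")
  invisible(c(fasta_file, gff3_file))
}

#' Write variant calls as VCF v4.2
#'
#' INFO keys: MAF, DP, LRTP, SBP, PASSLOW, PASSSTD, plus GENE/CSQ-style
#' annotation (`gene|category|impact|substitution`) when annotation
#' columns are present. FILTER is `PASS` for standard-stringency
#' calls, `lowMAF` for calls passing only the low-stringency gate, and
#' the failed gate names for audit rows.
#'
#' @param calls A call table from [call_variants()] (optionally
#'   annotated by [annotate_variants()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=haploscreen",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Mutant allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=LRTP,Number=1,Type=Float,Description=\"Likelihood-ratio p-value\">",
    "##INFO=<ID=SBP,Number=1,Type=Float,Description=\"Strand-bias p-value\">",
    "##INFO=<ID=PASSLOW,Number=1,Type=Integer,Description=\"Passes low-stringency (>=3% MAF) gates\">",
    "##INFO=<ID=PASSSTD,Number=1,Type=Integer,Description=\"Passes standard (>=7% MAF) gates\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"gene|category|impact|substitution\">",
    "##FILTER=<ID=lowMAF,Description=\"Below the standard 7% MAF cut-off\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls)) {
    filt <- ifelse(calls$passes_standard, "PASS",
                   ifelse(calls$passes_low, "lowMAF", "FAIL"))
    info <- sprintf("MAF=%.6g;DP=%d;LRTP=%.6g;SBP=%.6g;PASSLOW=%d;PASSSTD=%d",
                    calls$maf, calls$depth, calls$lrt_p, calls$strand_p,
                    as.integer(calls$passes_low),
                    as.integer(calls$passes_standard))
    if ("category" %in% names(calls)) {
      info <- paste0(info, sprintf(";CSQ=%s|%s|%s|%s",
                                   ifelse(is.na(calls$gene_id), ".", calls$gene_id),
                                   calls$category, calls$impact,
                                   ifelse(is.na(calls$substitution), ".",
                                          calls$substitution)))
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                       calls$contig, calls$pos, calls$ref, calls$alt,
                       filt, info), con)
  }
  invisible(path)
}
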