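#' Mutation spectra for chemical mutagens
#'
#' A mutation spectrum is a 4x4 base-substitution probability matrix
#' (rows = reference base, columns = alternate base) with a zero
#' diagonal and rows summing to 1. `enu_spectrum()` encodes the classic
#' ENU bias: A:T -> T:A and A:T -> G:C changes are weighted 3x over the
#' remaining substitutions, reflecting ENU's preference for mutating
#' A/T pairs. `uniform_spectrum()` assigns all three alternates equal
#' probability and is convenient for tests.
#'
#' @return A 4x4 numeric matrix with dimnames `c("A","C","G","T")`.
#' @examples
#' enu_spectrum()["A", ]
#' @export
enu_spectrum <- function() {
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  m["A", c("C", "G", "T")] <- c(1, 3, 3)   # A->G (A:T->G:C), A->T (A:T->T:A) favoured
  m["T", c("A", "C", "G")] <- c(3, 3, 1)   # complement strand of the above
  m["G", c("A", "C", "T")] <- 1
  m["C", c("A", "G", "T")] <- 1
  m / rowSums(m)
}

#' @rdname enu_spectrum
#' @export
uniform_spectrum <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- 0
  m
}

validate_spectrum <- function(spectrum) {
  if (!is.matrix(spectrum) || !identical(dim(spectrum), c(4L, 4L)) ||
      !identical(rownames(spectrum), BASES) ||
      !identical(colnames(spectrum), BASES)) {
    stop("spectrum must be a 4x4 matrix with dimnames A, C, G, T", call. = FALSE)
  }
  if (any(spectrum < 0) || any(diag(spectrum) != 0)) {
    stop("spectrum probabilities must be >= 0 with a zero diagonal", call. = FALSE)
  }
  if (any(abs(rowSums(spectrum) - 1) > 1e-9)) {
    stop("spectrum rows must each sum to 1", call. = FALSE)
  }
  invisible(spectrum)
}

random_cds <- function(n_codons) {
  codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste0, collapse = "")
  internal <- setdiff(codons, STOP_CODONS)
  body <- sample(internal, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste0(body, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a toy genome with simple gene models
#'
#' Builds a single-contig genome of `n_genes` single-exon genes, each a
#' complete open reading frame (ATG start, stop codon end) of
#' `gene_length_bp` coding bases, separated by `intergenic_bp` of random
#' intergenic sequence. Gene strands alternate (+, -, +, ...) so that
#' downstream annotation is exercised on both strands; on the minus
#' strand the genomic sequence holds the reverse complement of the
#' coding sequence.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_length_bp Coding length per gene; a multiple of 3, >= 9.
#' @param intergenic_bp Bases of random sequence between/flanking genes.
#' @param seed Integer seed; the genome is deterministic given the seed.
#' @param alternate_strands If `FALSE` all genes are on the plus strand.
#' @return An object of class `toy_genome`: a list with `contigs`
#'   (named character vector of uppercase sequences) and `cds` (a
#'   data.frame of 1-based closed CDS intervals with columns `gene_id`,
#'   `contig`, `strand`, `start`, `end`, `exon`).
#' @examples
#' g <- make_toy_genome(2, 30, 10, seed = 1)
#' g$cds
#' @export
make_toy_genome <- function(n_genes, gene_length_bp, intergenic_bp = 100L,
                            seed = 1L, alternate_strands = TRUE) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    stop("n_genes must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(gene_length_bp) || gene_length_bp < 9 ||
      gene_length_bp %% 3 != 0) {
    stop("gene_length_bp must be a multiple of 3 and >= 9", call. = FALSE)
  }
  if (!is.numeric(intergenic_bp) || intergenic_bp < 0) {
    stop("intergenic_bp must be >= 0", call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  gene_length_bp <- as.integer(gene_length_bp)
  intergenic_bp <- as.integer(intergenic_bp)
  set.seed(seed)

  pieces <- character(0)
  cds <- vector("list", n_genes)
  pos <- 0L
  spacer <- function(n) paste0(sample(BASES, n, replace = TRUE), collapse = "")
  for (i in seq_len(n_genes)) {
    pieces <- c(pieces, spacer(intergenic_bp))
    pos <- pos + intergenic_bp
    strand <- if (alternate_strands && i %% 2L == 0L) "-" else "+"
    coding <- random_cds(gene_length_bp %/% 3L)
    genomic <- if (strand == "-") revcomp(coding) else coding
    pieces <- c(pieces, genomic)
    cds[[i]] <- data.frame(
      gene_id = sprintf("g%03d", i), contig = "chr1", strand = strand,
      start = pos + 1L, end = pos + gene_length_bp, exon = 1L,
      stringsAsFactors = FALSE
    )
    pos <- pos + gene_length_bp
  }
  pieces <- c(pieces, spacer(intergenic_bp))
  genome <- structure(
    list(contigs = c(chr1 = paste0(pieces, collapse = "")),
         cds = do.call(rbind, cds)),
    class = "toy_genome"
  )
  genome
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d contig(s), %d bp total, %d gene(s)\n",
              length(x$contigs), sum(nchar(x$contigs)),
              length(unique(x$cds$gene_id))))
  invisible(x)
}

genome_base <- function(genome, contig, pos) {
  substring(genome$contigs[[contig]], pos, pos)
}

#' Construct an SNV table
#'
#' The atomic variant record carried from simulation through ranking:
#' one row per single-nucleotide variant with 1-based position.
#'
#' @param contig,pos,ref,alt Parallel vectors describing the variants.
#' @return A data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @export
snv_table <- function(contig = character(), pos = integer(),
                      ref = character(), alt = character()) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$pos < 1L)) stop("positions are 1-based; got pos < 1", call. = FALSE)
    if (any(!df$ref %in% BASES) || any(!df$alt %in% BASES)) {
      stop("ref and alt must be single bases A/C/G/T", call. = FALSE)
    }
    if (any(df$ref == df$alt)) stop("ref and alt must differ", call. = FALSE)
    df <- df[order(df$contig, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
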