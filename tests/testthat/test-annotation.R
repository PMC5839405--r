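# ATG GCA TGG TAT TAA : M A W Y *
PLUS_CONTIG <- paste0("TTTT", "ATGGCATGGTATTAA", "TTTT")
PLUS_CDS <- data.frame(gene_id = "gA", contig = "chr1", strand = "+",
                       start = 5L, end = 19L, stringsAsFactors = FALSE)

test_that("codon-level consequences follow the genetic code", {
  m <- gms(PLUS_CONTIG, PLUS_CDS)
  ann <- function(pos, ref, alt) {
    annotate_variants(snv_table("chr1", pos, ref, alt), m)
  }
  # GCA -> ACA: missense Ala -> Thr at residue 2
  a <- ann(8, "G", "A")
  expect_equal(a$category, "missense")
  expect_equal(a$impact, "moderate")
  expect_equal(a$ref_aa, "A"); expect_equal(a$alt_aa, "T")
  expect_equal(a$protein_pos, 2L)
  expect_equal(a$substitution, "A2T")
  # GCA -> GCG: synonymous, low impact
  s <- ann(10, "A", "G")
  expect_equal(s$category, "synonymous")
  expect_equal(s$impact, "low")
  # TGG -> TGA: stop gained, high impact
  st <- ann(13, "G", "A")
  expect_equal(st$category, "stop_gained")
  expect_equal(st$impact, "high")
  expect_equal(st$substitution, "W3*")
  # TAA -> CAA: stop lost, high impact
  sl <- ann(17, "T", "C")
  expect_equal(sl$category, "stop_lost")
  expect_equal(sl$impact, "high")
  # intergenic flank
  ig <- ann(2, "T", "A")
  expect_equal(ig$category, "intergenic")
  expect_equal(ig$impact, "none")
  expect_true(is.na(ig$gene_id))
  # reference mismatch is an input error
  expect_error(annotate_variants(snv_table("chr1", 8, "C", "A"), m),
               "ref mismatch")
})

test_that("splice sites span 2 intronic bases at internal CDS edges", {
  # exon1 5..13 (ATG GCA TGG), intron 14..23, exon2 24..29 (TAT TAA)
  contig <- paste0("TTTT", "ATGGCATGG", "GTTTTTTTAG", "TATTAA", "TTTT")
  cds <- data.frame(gene_id = "gB", contig = "chr1", strand = "+",
                    start = c(5L, 24L), end = c(13L, 29L),
                    stringsAsFactors = FALSE)
  m <- gms(contig, cds)
  cat_at <- function(pos) {
    ref <- substring(contig, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    annotate_variants(snv_table("chr1", pos, ref, alt), m)$category
  }
  expect_equal(cat_at(14), "splice_site")  # donor +1
  expect_equal(cat_at(15), "splice_site")  # donor +2
  expect_equal(cat_at(16), "intronic")
  expect_equal(cat_at(21), "intronic")
  expect_equal(cat_at(22), "splice_site")  # acceptor -2
  expect_equal(cat_at(23), "splice_site")  # acceptor -1
  expect_equal(annotate_variants(snv_table("chr1", 14, "G", "A"), m)$impact,
               "high")
  # coding positions still annotate through the spliced frame
  a <- annotate_variants(snv_table("chr1", 24, "T", "C"), m)
  expect_equal(a$protein_pos, 4L)
})

test_that("minus-strand annotation mirrors the plus-strand construction", {
  # same gene built in both orientations: residue-for-residue agreement
  coding_contig <- PLUS_CONTIG
  minus_contig <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(coding_contig)
  ))
  L <- nchar(coding_contig)
  minus_cds <- data.frame(gene_id = "gA", contig = "chr1", strand = "-",
                          start = L - 19L + 1L, end = L - 5L + 1L,
                          stringsAsFactors = FALSE)
  mp <- gms(coding_contig, PLUS_CDS)
  mm <- gms(minus_contig, minus_cds)
  for (pos in 5:19) {
    ref <- substring(coding_contig, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a_plus <- annotate_variants(snv_table("chr1", pos, ref, alt), mp)
      mpos <- L - pos + 1L
      a_minus <- annotate_variants(
        snv_table("chr1", mpos, chartr("ACGT", "TGCA", ref),
                  chartr("ACGT", "TGCA", alt)), mm)
      expect_equal(a_minus$category, a_plus$category)
      expect_equal(a_minus$protein_pos, a_plus$protein_pos)
      expect_equal(a_minus$ref_aa, a_plus$ref_aa)
      expect_equal(a_minus$alt_aa, a_plus$alt_aa)
    }
  }
})

test_that("all SNVs of a 9-codon gene agree with the translate-and-compare oracle", {
  for (which_gene in 1:2) {  # gene 1 is +, gene 2 is -
    g <- make_toy_genome(2, 27, 10, seed = 21)
    models <- gene_models(g)
    rows <- g$cds[g$cds$gene_id == sprintf("g%03d", which_gene), ]
    for (pos in seq(rows$start, rows$end)) {
      ref <- substring(g$contigs[[1]], pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- annotate_variants(snv_table("chr1", pos, ref, alt),
                                 models)$category
        want <- oracle_consequence(g, rows, rows$strand[1], pos, alt)
        expect_equal(got, want,
                     info = sprintf("gene %d pos %d %s>%s",
                                    which_gene, pos, ref, alt))
      }
    }
  }
})

test_that("gene models load from GFF3 + FASTA and round-trip the generator", {
  g <- make_toy_genome(4, 99, 30, seed = 13)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome_files(g, fa, gff)
  loaded <- load_gene_models(gff, fa)
  native <- gene_models(g)
  expect_setequal(names(loaded$genes), names(native$genes))
  for (gid in names(native$genes)) {
    expect_equal(loaded$genes[[gid]]$cds_seq, native$genes[[gid]]$cds_seq)
    expect_equal(loaded$genes[[gid]]$strand, native$genes[[gid]]$strand)
    expect_equal(loaded$genes[[gid]]$cds_length,
                 native$genes[[gid]]$cds_length)
  }
})

test_that("invalid gene models are rejected with the gene named", {
  expect_error(
    gms(strrep("A", 50),
        data.frame(gene_id = "gBad", contig = "chr1", strand = "+",
                   start = 5L, end = 14L)),   # length 10
    "gBad.*not a multiple of 3")
  expect_error(
    gms(strrep("A", 20),
        data.frame(gene_id = "gOut", contig = "chr1", strand = "+",
                   start = 10L, end = 30L)),
    "gOut.*bounds")
  expect_error(
    gms(strrep("A", 50),
        data.frame(gene_id = "gOv", contig = "chr1", strand = "+",
                   start = c(5L, 10L), end = c(13L, 18L))),
    "gOv.*overlap")
})

test_that("effect filtering keeps moderate and high impacts only", {
  df <- data.frame(impact = c("moderate", "low", "high", "none"),
                   category = c("missense", "synonymous", "stop_gained",
                                "intergenic"))
  kept <- filter_effect(df)
  expect_setequal(kept$category, c("missense", "stop_gained"))
  expect_equal(nrow(filter_effect(df[df$impact == "low", ])), 0L)
  expect_equal(nrow(filter_effect(df[0, ])), 0L)
})

test_that("substitutions format in one-letter notation", {
  cons <- data.frame(category = c("missense", "missense", "stop_gained"),
                     ref_aa = c("F", "I", "W"),
                     protein_pos = c(256L, 764L, 10L),
                     alt_aa = c("L", "N", "*"), stringsAsFactors = FALSE)
  expect_equal(format_substitution(cons), c("F256L", "I764N", "W10*"))
  bad <- data.frame(category = "synonymous", ref_aa = "A",
                    protein_pos = 1L, alt_aa = "A")
  expect_error(format_substitution(bad), "protein-altering")
})
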