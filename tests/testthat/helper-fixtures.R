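# Small fixtures built in code.

# a genome shell without gene models, for pooled-count simulations
bare_genome <- function(seq) {
  structure(list(
    contigs = c(chr1 = seq),
    cds = data.frame(gene_id = character(), contig = character(),
                     strand = character(), start = integer(),
                     end = integer(), exon = integer(),
                     stringsAsFactors = FALSE)
  ), class = "toy_genome")
}

make_clone <- function(id, snvs = snv_table(), resistant = FALSE) {
  list(clone_id = id, snvs = snvs, is_resistant = resistant)
}

# gene model set straight from a contig string and CDS intervals
gms <- function(contig_seq, cds_df) {
  haploscreen:::new_gene_model_set(cds_df, c(chr1 = contig_seq))
}

counts_row <- function(pos, ref, alt, depth, alt_fwd, alt_rev,
                       contig = "chr1") {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             depth = as.integer(depth), alt_fwd = as.integer(alt_fwd),
             alt_rev = as.integer(alt_rev), stringsAsFactors = FALSE)
}

# pool where clone 1 carries the same private alt at `n_sites`
# consecutive positions of an all-A contig; the remaining clones are
# variant-free
private_variant_pool <- function(n_sites, n_clones = 10, mean_depth = 150,
                                 seq_error = 0, seed = 1) {
  genome <- bare_genome(strrep("A", n_sites))
  carrier <- make_clone("clone01",
                        snv_table("chr1", seq_len(n_sites),
                                  rep("A", n_sites), rep("G", n_sites)))
  others <- lapply(seq_len(n_clones - 1L), function(i) {
    make_clone(sprintf("clone%02d", i + 1L))
  })
  sample_pool_counts(c(list(carrier), others), genome,
                     mean_depth = mean_depth, seq_error = seq_error,
                     seed = seed)
}
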