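# ENU mutagenesis of haploid clones and screen assembly.

#' Draw random ENU-induced SNVs on a genome
#'
#' Each base mutates independently with probability `per_base_rate`;
#' the alternate base is drawn from the spectrum row of the reference
#' base. At most one SNV arises per position (haploid genome).
#'
#' @param genome A [make_toy_genome()] object.
#' @param per_base_rate Per-base mutation probability in `[0, 1)`.
#' @param spectrum A base-substitution matrix, see [enu_spectrum()].
#' @param seed Integer seed (optional; `NULL` uses the current RNG state).
#' @return An [snv_table()] of induced variants.
#' @export
draw_enu_mutations <- function(genome, per_base_rate,
                               spectrum = enu_spectrum(), seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  if (!is.numeric(per_base_rate) || per_base_rate < 0 || per_base_rate >= 1) {
    stop("per_base_rate must be in [0, 1)", call. = FALSE)
  }
  validate_spectrum(spectrum)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (contig in names(genome$contigs)) {
    seq <- genome$contigs[[contig]]
    L <- nchar(seq)
    hits <- which(runif(L) < per_base_rate)
    if (!length(hits)) next
    ref <- substring(seq, hits, hits)
    alt <- character(length(hits))
    for (b in BASES) {
      idx <- which(ref == b)
      if (length(idx)) {
        alt[idx] <- sample(BASES, length(idx), replace = TRUE,
                           prob = spectrum[b, ])
      }
    }
    out[[contig]] <- snv_table(contig, hits, ref, alt)
  }
  if (!length(out)) return(snv_table())
  do.call(rbind, out)
}

draw_causal_allele <- function(genome, models, causal_gene, taken_pos) {
  gene <- models$genes[[causal_gene]]
  cds_positions <- unlist(lapply(seq_len(nrow(gene$cds)), function(j) {
    seq.int(gene$cds$start[[j]], gene$cds$end[[j]])
  }))
  for (attempt in seq_len(10000L)) {
    pos <- sample(cds_positions, 1L)
    if (pos %in% taken_pos) next
    ref <- genome_base(genome, gene$contig, pos)
    alt <- sample(setdiff(BASES, ref), 1L)
    cons <- annotate_one(gene$contig, pos, ref, alt, models)
    if (identical(cons$gene_id, causal_gene) &&
        cons$impact %in% c("moderate", "high") &&
        cons$category %in% c("missense", "stop_gained")) {
      return(snv_table(gene$contig, pos, ref, alt))
    }
  }
  stop("could not place a non-synonymous causal allele; CDS too constrained",
       call. = FALSE)
}

#' Assemble a synthetic suppressor screen
#'
#' Creates `n_clones` independently ENU-mutagenized haploid clones. The
#' first `n_resistant` clones each carry one causal non-synonymous SNV
#' in `causal_gene`'s CDS; with `shared_multiplicity = m >= 2` the first
#' m resistant clones share a single causal allele (the pooled signal of
#' a variant recovered from several clones), all remaining causal
#' alleles are private and at distinct positions. Clone pool fractions
#' default to equal; a Dirichlet concentration can skew them the way
#' real pooling never mixes clones exactly evenly.
#'
#' @param genome A [make_toy_genome()] object.
#' @param n_clones Clones in the pool (screen design: 10).
#' @param causal_gene Gene id in `genome` receiving causal alleles.
#' @param n_resistant Clones carrying a causal allele (`<= n_clones`).
#' @param per_base_rate Background ENU rate per base per clone.
#' @param spectrum Mutation spectrum, see [enu_spectrum()].
#' @param proportions `"equal"` or a numeric vector summing to 1.
#' @param shared_multiplicity Clones sharing the first causal allele
#'   (1 = all causal alleles private).
#' @param dirichlet_alpha If non-`NULL`, pool fractions are drawn from
#'   a symmetric Dirichlet with this concentration (overrides
#'   `proportions`).
#' @param seed Integer seed.
#' @return A list with `clones` (each a list `clone_id`, `snvs`,
#'   `is_resistant`) and `truth` (class `screen_truth`: `causal_gene`,
#'   `causal_snvs` with `clone_id` column, `proportions`,
#'   `background`).
#' @export
build_screen <- function(genome, n_clones, causal_gene, n_resistant,
                         per_base_rate, spectrum = enu_spectrum(),
                         proportions = "equal", shared_multiplicity = 1L,
                         dirichlet_alpha = NULL, seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"))
  if (n_resistant > n_clones) {
    stop("n_resistant must be <= n_clones", call. = FALSE)
  }
  models <- gene_models(genome)
  if (n_resistant > 0L && !causal_gene %in% names(models$genes)) {
    stop(sprintf("causal gene '%s' not found in genome", causal_gene),
         call. = FALSE)
  }
  if (shared_multiplicity < 1L ||
      (n_resistant > 0L && shared_multiplicity > n_resistant)) {
    stop("shared_multiplicity must be in [1, n_resistant]", call. = FALSE)
  }
  validate_spectrum(spectrum)
  set.seed(seed)

  # pool fractions
  props <- if (!is.null(dirichlet_alpha)) {
    g <- rgamma(n_clones, shape = dirichlet_alpha)
    g / sum(g)
  } else if (identical(proportions, "equal")) {
    rep(1 / n_clones, n_clones)
  } else {
    if (length(proportions) != n_clones) {
      stop("proportions must have one entry per clone", call. = FALSE)
    }
    if (abs(sum(proportions) - 1) > 1e-6) {
      stop("proportions must sum to 1", call. = FALSE)
    }
    as.numeric(proportions)
  }
  clone_ids <- sprintf("clone%02d", seq_len(n_clones))
  names(props) <- clone_ids

  # causal alleles: allele 1 shared by shared_multiplicity clones,
  # the rest private, all at distinct positions
  n_alleles <- if (n_resistant == 0L) 0L else {
    n_resistant - shared_multiplicity + 1L
  }
  alleles <- list()
  taken <- integer(0)
  for (a in seq_len(n_alleles)) {
    alleles[[a]] <- draw_causal_allele(genome, models, causal_gene, taken)
    taken <- c(taken, alleles[[a]]$pos)
  }
  causal_of <- rep(list(NULL), n_clones)
  if (n_alleles > 0L) {
    for (k in seq_len(shared_multiplicity)) causal_of[[k]] <- alleles[[1L]]
    extra <- setdiff(seq_len(n_resistant), seq_len(shared_multiplicity))
    for (i in seq_along(extra)) causal_of[[extra[[i]]]] <- alleles[[i + 1L]]
  }

  clone_seeds <- sample.int(.Machine$integer.max - 1L, n_clones)
  clones <- vector("list", n_clones)
  background <- list()
  causal_rows <- list()
  for (i in seq_len(n_clones)) {
    bg <- draw_enu_mutations(genome, per_base_rate, spectrum,
                             seed = clone_seeds[[i]])
    causal <- causal_of[[i]]
    snvs <- bg
    if (!is.null(causal)) {
      # haploidy: the causal allele replaces any background SNV there
      snvs <- bg[!(bg$contig == causal$contig & bg$pos == causal$pos), ,
                 drop = FALSE]
      snvs <- rbind(snvs, causal)
      snvs <- snvs[order(snvs$contig, snvs$pos), , drop = FALSE]
      rownames(snvs) <- NULL
      causal_rows[[clone_ids[[i]]]] <- cbind(
        data.frame(clone_id = clone_ids[[i]], stringsAsFactors = FALSE),
        causal
      )
    }
    if (nrow(bg)) {
      background[[clone_ids[[i]]]] <- cbind(
        data.frame(clone_id = clone_ids[[i]], stringsAsFactors = FALSE), bg
      )
    }
    clones[[i]] <- list(clone_id = clone_ids[[i]], snvs = snvs,
                        is_resistant = !is.null(causal))
  }
  empty_clone_df <- cbind(data.frame(clone_id = character()), snv_table())
  truth <- structure(
    list(
      causal_gene = if (n_resistant > 0L) causal_gene else NA_character_,
      causal_snvs = if (length(causal_rows)) {
        do.call(rbind, unname(causal_rows))
      } else empty_clone_df,
      proportions = props,
      background = if (length(background)) {
        do.call(rbind, unname(background))
      } else empty_clone_df
    ),
    class = "screen_truth"
  )
  rownames(truth$causal_snvs) <- NULL
  rownames(truth$background) <- NULL
  list(clones = clones, truth = truth)
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf(
    "screen_truth: causal gene %s; %d causal SNV record(s); %d clone(s)\n",
    x$causal_gene, nrow(x$causal_snvs), length(x$proportions)))
  invisible(x)
}
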