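# Independent brute-force oracles, kept free of the package's own
# computation paths.

# direct binomial log-likelihood, written out termwise
oracle_loglik <- function(alt, depth, p) {
  term <- function(k, q) if (k == 0L) 0 else k * log(q)
  lchoose(depth, alt) + term(alt, p) + term(depth - alt, 1 - p)
}

oracle_lrt <- function(depth, alt, error) {
  maf <- alt / depth
  if (maf <= error) return(0)
  2 * (oracle_loglik(alt, depth, maf) - oracle_loglik(alt, depth, error))
}

# exact two-sided binomial p: sum of all outcome probabilities not
# exceeding the observed one (with the standard relative fudge)
oracle_binom_two_sided <- function(x, n, p) {
  if (n == 0L) return(1)
  d <- dbinom(0:n, n, p)
  min(1, sum(d[d <= d[[x + 1L]] * (1 + 1e-7)]))
}

# brute-force consequence of a single SNV: mutate the contig string,
# re-extract and re-translate the full protein with seqinr, and compare
oracle_consequence <- function(genome, gene_cds, strand, pos, alt) {
  seq <- genome$contigs[["chr1"]]
  mutated <- seq
  substring(mutated, pos, pos) <- alt
  extract <- function(s) {
    pieces <- substring(s, gene_cds$start, gene_cds$end)
    cds <- paste0(pieces, collapse = "")
    if (strand == "-") {
      cds <- paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]),
                   collapse = "")
    }
    cds
  }
  translate_str <- function(cds) {
    seqinr::translate(strsplit(cds, "")[[1]])
  }
  ref_prot <- translate_str(extract(seq))
  alt_prot <- translate_str(extract(mutated))
  diff <- which(ref_prot != alt_prot)
  if (!length(diff)) return("synonymous")
  k <- diff[[1L]]
  if (alt_prot[[k]] == "*") return("stop_gained")
  if (ref_prot[[k]] == "*") return("stop_lost")
  "missense"
}

# all-pairs exhaustive minimum distance between two coordinate sets
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# random proper rotation + translation applied to a structure_complex
rigid_transform_complex <- function(cx, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 20)
  apply_rt <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[[1]]
    df$y <- xyz[, 2] + shift[[2]]
    df$z <- xyz[, 3] + shift[[3]]
    df
  }
  cx$protein <- apply_rt(cx$protein)
  cx$ligand <- apply_rt(cx$ligand)
  cx
}
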