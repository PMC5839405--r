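# Pooled sequencing of haploid clones at count level.
#
# Depth is Poisson around the design mean; every read is drawn from a
# clone according to the pool fractions, reports that clone's allele,
# and is miscalled to each of the three other bases with probability
# seq_error/3; strands are assigned forward with probability
# fwd_fraction. The abstraction starts downstream of alignment: one
# count record per site, no read-level artefacts.

#' Simulate pooled per-site allele counts
#'
#' Emits records for every site carrying a clone variant (always) or
#' miscalled-base evidence (one record per observed non-reference
#' base); `all_sites = TRUE` additionally emits zero-evidence sites
#' (alt `"."`), which is what a global error estimate needs as its
#' denominator. At clone-variant sites the record tracks the clone
#' allele — the most strongly supported one if several segregate.
#'
#' @param clones List of clones from [build_screen()].
#' @param genome The [make_toy_genome()] object the clones derive from.
#' @param proportions `"equal"` or a numeric vector summing to 1, one
#'   entry per clone.
#' @param mean_depth Mean sequencing depth (design: 150).
#' @param seq_error Per-read miscall probability, in `[0, 0.01]`.
#' @param fwd_fraction Probability a read is on the forward strand.
#' @param seed Integer seed (optional).
#' @param all_sites Emit every genomic site, including zero-evidence
#'   ones.
#' @return A data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_fwd`, `alt_rev` (1-based positions).
#' @export
sample_pool_counts <- function(clones, genome, proportions = "equal",
                               mean_depth = 150, seq_error = 0.001,
                               fwd_fraction = 0.5, seed = NULL,
                               all_sites = FALSE) {
  stopifnot(inherits(genome, "toy_genome"), is.list(clones))
  n <- length(clones)
  props <- if (identical(proportions, "equal")) rep(1 / n, n) else {
    as.numeric(proportions)
  }
  if (length(props) != n) {
    stop("proportions must have one entry per clone", call. = FALSE)
  }
  if (abs(sum(props) - 1) > 1e-6) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  if (seq_error < 0 || seq_error > 0.01) {
    stop("seq_error must be in [0, 0.01]", call. = FALSE)
  }
  if (fwd_fraction <= 0 || fwd_fraction >= 1) {
    stop("fwd_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  e3 <- seq_error / 3

  # clone variants grouped per site
  per_clone <- Filter(Negate(is.null), lapply(seq_len(n), function(i) {
    s <- clones[[i]]$snvs
    if (!nrow(s)) return(NULL)
    cbind(s, prop = props[[i]])
  }))
  var_tab <- if (length(per_clone)) do.call(rbind, per_clone) else NULL
  out <- list()

  for (contig in names(genome$contigs)) {
    seq <- genome$contigs[[contig]]
    L <- nchar(seq)
    vt <- if (!is.null(var_tab)) {
      var_tab[var_tab$contig == contig, , drop = FALSE]
    } else var_tab
    var_pos <- if (!is.null(vt)) sort(unique(vt$pos)) else integer(0)

    # --- error-only sites, vectorized ---
    pos <- setdiff(seq_len(L), var_pos)
    depth <- rpois(length(pos), mean_depth)
    if (seq_error > 0) {
      n1 <- rbinom(length(pos), depth, e3)
      n2 <- rbinom(length(pos), depth - n1, e3 / (1 - e3))
      n3 <- rbinom(length(pos), depth - n1 - n2, e3 / (1 - 2 * e3))
      counts <- cbind(n1, n2, n3)
    } else {
      counts <- matrix(0L, length(pos), 3L)
    }
    # one record per (site, miscalled base with evidence); zero-evidence
    # sites are emitted once with alt "." when all_sites is set
    nonref <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
    any_ev <- counts[, 1L] > 0L | counts[, 2L] > 0L | counts[, 3L] > 0L
    for (slot in 1:3) {
      keep <- counts[, slot] > 0L
      if (!any(keep)) next
      ref <- substring(seq, pos[keep], pos[keep])
      at <- counts[keep, slot]
      af <- rbinom(sum(keep), at, fwd_fraction)
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, pos = pos[keep], ref = ref,
        alt = nonref[cbind(match(ref, BASES), slot)],
        depth = depth[keep], alt_fwd = af, alt_rev = at - af,
        stringsAsFactors = FALSE
      )
    }
    if (all_sites && any(!any_ev)) {
      ref <- substring(seq, pos[!any_ev], pos[!any_ev])
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, pos = pos[!any_ev], ref = ref, alt = ".",
        depth = depth[!any_ev], alt_fwd = 0L, alt_rev = 0L,
        stringsAsFactors = FALSE
      )
    }

    # --- clone-variant sites, one by one ---
    if (length(var_pos)) {
      rows <- vector("list", length(var_pos))
      for (k in seq_along(var_pos)) {
        p <- var_pos[[k]]
        here <- vt[vt$pos == p, , drop = FALSE]
        alleles <- unique(here$alt)
        p_allele <- vapply(alleles, function(a) {
          sum(here$prop[here$alt == a])
        }, numeric(1L))
        d <- rpois(1L, mean_depth)
        intended <- as.integer(rmultinom(1L, d, c(p_allele, 1 - sum(p_allele))))
        final <- integer(length(alleles))
        for (j in seq_along(alleles)) {
          final[[j]] <- rbinom(1L, intended[[j]], 1 - seq_error) +
            rbinom(1L, d - intended[[j]], e3)
        }
        pick <- which.max(final)  # ties resolved to the first allele
        at <- final[[pick]]
        af <- rbinom(1L, at, fwd_fraction)
        rows[[k]] <- data.frame(
          contig = contig, pos = p, ref = here$ref[[1L]],
          alt = alleles[[pick]], depth = d, alt_fwd = af, alt_rev = at - af,
          stringsAsFactors = FALSE
        )
      }
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_fwd = integer(),
                      alt_rev = integer(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$contig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Expected pooled mutant allele frequency
#'
#' In a pool of `n_clones` equally represented haploid clones, a
#' variant carried by `m_clones` of them contributes an expected mutant
#' allele fraction of `m/n` — 10% for a private variant in a 10-clone
#' pool.
#'
#' @param m_clones Clones carrying the variant (`1 <= m <= n`).
#' @param n_clones Clones in the pool.
#' @return The expected allele fraction `m/n`.
#' @examples
#' expected_pool_maf(1, 10)  # 0.1
#' @export
expected_pool_maf <- function(m_clones, n_clones) {
  if (any(m_clones < 1) || any(m_clones > n_clones)) {
    stop("require 1 <= m_clones <= n_clones", call. = FALSE)
  }
  m_clones / n_clones
}
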