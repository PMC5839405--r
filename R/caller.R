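# Probabilistic low-frequency variant calling for pooled counts.
#
# A site is called when four gates agree: coverage (depth >= 50),
# a binomial likelihood-ratio test of the observed allele fraction
# against the globally estimated sequencing error, an exact two-sided
# binomial strand-bias test, and the mutant-allele-frequency cut-off
# (low stringency >= 3%, standard >= 7%).

#' Caller parameters
#'
#' @param min_depth Minimum read depth (default 50).
#' @param maf_low Low-stringency mutant allele frequency cut-off
#'   (default 0.03).
#' @param maf_standard Standard cut-off (default 0.07); must be
#'   `>= maf_low`.
#' @param lrt_alpha Significance level of the likelihood-ratio test
#'   (default 1e-6, an approximate exome-wide Bonferroni level).
#' @param strand_alpha Strand-bias rejection level: calls with a
#'   two-sided strand p-value below this are filtered (default 0.01).
#' @param error_floor Lower clamp for the global error rate.
#' @param maf_ceiling Sites below this allele fraction feed the global
#'   error estimate (default 0.01).
#' @param fwd_fraction Expected forward-strand fraction (default 0.5).
#' @return A validated list of class `caller_params`.
#' @export
caller_params <- function(min_depth = 50L, maf_low = 0.03,
                          maf_standard = 0.07, lrt_alpha = 1e-6,
                          strand_alpha = 0.01, error_floor = 1e-6,
                          maf_ceiling = 0.01, fwd_fraction = 0.5) {
  if (!(maf_low > 0 && maf_low <= maf_standard && maf_standard < 1)) {
    stop("require 0 < maf_low <= maf_standard < 1", call. = FALSE)
  }
  if (min_depth < 1) stop("min_depth must be >= 1", call. = FALSE)
  if (!(lrt_alpha > 0 && lrt_alpha < 1 && strand_alpha > 0 && strand_alpha < 1)) {
    stop("alphas must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(min_depth = as.integer(min_depth), maf_low = maf_low,
                 maf_standard = maf_standard, lrt_alpha = lrt_alpha,
                 strand_alpha = strand_alpha, error_floor = error_floor,
                 maf_ceiling = maf_ceiling, fwd_fraction = fwd_fraction),
            class = "caller_params")
}

#' Estimate the global sequencing error rate
#'
#' Pools alternate-allele evidence across sites whose allele fraction
#' is below `maf_ceiling` (i.e. sites compatible with pure sequencing
#' error) and returns the aggregate rate sum(alt)/sum(depth), clamped
#' below by `error_floor`. Feed it a counts table that includes
#' zero-evidence sites (see `all_sites` in [sample_pool_counts()]) so
#' the denominator reflects all error-free depth.
#'
#' @param counts Counts table (`contig`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_fwd`, `alt_rev`).
#' @param maf_ceiling Upper allele-fraction bound for qualifying sites.
#' @param error_floor Lower clamp of the returned rate.
#' @return The estimated per-read error rate.
#' @export
estimate_global_error <- function(counts, maf_ceiling = 0.01,
                                  error_floor = 1e-6) {
  if (!nrow(counts)) stop("counts table is empty", call. = FALSE)
  # aggregate per site: alt evidence may be split over per-base records
  key <- paste(counts$contig, counts$pos)
  alt <- as.vector(tapply(counts$alt_fwd + counts$alt_rev, key, sum))
  depth <- as.vector(tapply(counts$depth, key, max))
  ok <- depth > 0 & alt / depth < maf_ceiling
  if (!any(ok)) {
    stop("no sites below the MAF ceiling; supply a larger input ",
         "(include zero-evidence sites)", call. = FALSE)
  }
  max(error_floor, sum(alt[ok]) / sum(depth[ok]))
}

#' Binomial likelihood-ratio test against the error rate
#'
#' Tests H0: alt ~ Binomial(depth, error) against H1: alt ~
#' Binomial(depth, alt/depth). The statistic 2*(logL1 - logL0) is
#' clamped to 0 when the observed fraction does not exceed the error
#' rate (one-sided alternative); the p-value is the upper chi-square
#' tail with 1 df.
#'
#' @param depth,alt Integer vectors of site depth and alternate count.
#' @param error Global per-read error rate.
#' @return A data.frame with columns `lrt_stat` and `lrt_p`.
#' @export
likelihood_ratio_call <- function(depth, alt, error) {
  if (any(depth <= 0)) stop("depth must be > 0 at tested sites", call. = FALSE)
  maf <- alt / depth
  stat <- ifelse(
    maf <= error, 0,
    2 * (dbinom(alt, depth, maf, log = TRUE) -
           dbinom(alt, depth, error, log = TRUE))
  )
  data.frame(lrt_stat = stat, lrt_p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Exact two-sided strand-bias test
#'
#' Exact binomial test of the forward alternate count out of the total
#' alternate count against the expected forward fraction. Zero
#' alternate reads return p = 1 by contract (nothing to test).
#'
#' @param alt_fwd,alt_rev Integer vectors of stranded alternate counts.
#' @param fwd_fraction Expected forward-strand fraction.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @export
strand_bias_test <- function(alt_fwd, alt_rev, fwd_fraction = 0.5) {
  n <- alt_fwd + alt_rev
  vapply(seq_along(n), function(i) {
    if (n[[i]] == 0L) return(1)
    binom.test(alt_fwd[[i]], n[[i]], p = fwd_fraction)$p.value
  }, numeric(1L))
}

#' Call variants in a pooled counts table
#'
#' Applies the four gates conjunctively: depth >= `min_depth`,
#' likelihood-ratio p <= `lrt_alpha`, strand p >= `strand_alpha`, and
#' MAF >= `maf_low`; `passes_standard` additionally requires MAF >=
#' `maf_standard`. Records without a single-base alternate allele
#' (no-evidence sites, indel-style alleles) are discarded.
#'
#' @param counts Counts table as from [sample_pool_counts()] or
#'   [read_counts_tsv()].
#' @param params A [caller_params()] object.
#' @param error Global error rate; estimated from `counts` with
#'   [estimate_global_error()] when `NULL`.
#' @param keep_all Return all evaluated sites with their gate flags
#'   instead of only passing calls.
#' @return A data.frame of calls: the count columns plus `maf`,
#'   `lrt_stat`, `lrt_p`, `strand_p`, `passes_low`, `passes_standard`,
#'   `in_control`, with the error rate used in attribute
#'   `"global_error"`.
#' @export
call_variants <- function(counts, params = caller_params(), error = NULL,
                          keep_all = FALSE) {
  stopifnot(inherits(params, "caller_params"))
  if (is.null(error)) {
    error <- estimate_global_error(counts, params$maf_ceiling,
                                   params$error_floor)
  }
  snv <- counts$alt %in% BASES & counts$ref %in% BASES &
    nchar(counts$alt) == 1L & nchar(counts$ref) == 1L & counts$depth > 0
  x <- counts[snv, , drop = FALSE]
  alt <- x$alt_fwd + x$alt_rev
  x$maf <- ifelse(x$depth > 0, alt / x$depth, 0)
  lrt <- likelihood_ratio_call(x$depth, alt, error)
  x$lrt_stat <- lrt$lrt_stat
  x$lrt_p <- lrt$lrt_p
  x$strand_p <- strand_bias_test(x$alt_fwd, x$alt_rev, params$fwd_fraction)
  x$passes_low <- x$depth >= params$min_depth &
    x$lrt_p <= params$lrt_alpha &
    x$strand_p >= params$strand_alpha &
    x$maf >= params$maf_low
  x$passes_standard <- x$passes_low & x$maf >= params$maf_standard
  x$in_control <- FALSE
  if (!keep_all) x <- x[x$passes_low, , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "global_error") <- error
  x
}

#' Subtract control-pool calls from a treated pool
#'
#' Removes treated calls whose (contig, position, alternate allele)
#' also appears in the control calls — the mutagenized-but-unselected
#' pool that captures mutagenesis background and fixed differences.
#'
#' @param treated,control Call tables from [call_variants()] on pools
#'   from the same genome.
#' @return A list with `calls` (retained treated calls) and `removed`
#'   (subtracted calls flagged `in_control = TRUE`).
#' @export
subtract_control <- function(treated, control) {
  if (nrow(treated) && nrow(control) &&
      !length(intersect(unique(treated$contig), unique(control$contig)))) {
    stop("treated and control calls share no contigs; ",
         "are they from the same genome?", call. = FALSE)
  }
  key <- function(df) paste(df$contig, df$pos, df$alt, sep = ":")
  hit <- key(treated) %in% key(control)
  removed <- treated[hit, , drop = FALSE]
  if (nrow(removed)) removed$in_control <- TRUE
  kept <- treated[!hit, , drop = FALSE]
  rownames(kept) <- NULL
  rownames(removed) <- NULL
  list(calls = kept, removed = removed)
}
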