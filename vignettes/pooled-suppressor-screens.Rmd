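---
title: "Pooled suppressor-screen analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled suppressor-screen analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscreen)
```

## The screen and its statistical model

A chemical suppressor screen in haploid cells works in three steps:
random single-nucleotide mutagenesis (ENU), selection with a toxic
compound, and pooled sequencing of the surviving clones. Haploidy means
every induced allele is immediately exposed; pooling N resistant clones
into one sequencing library means a causal variant private to one clone
is expected at a mutant allele frequency (MAF) of 1/N — 10% in the
10-clone design — and an allele shared by m clones at m/N. The causal
gene is then the one that accumulates *independent* protein-altering
alleles, because each resistant clone acquired its own mutation in the
same target.

`haploscreen` models the pooled counts at a site as follows. Depth is
Poisson around the design mean. Each read is drawn from a clone
according to the pool fractions and reports that clone's allele; with
probability `seq_error` the read is miscalled, uniformly to one of the
three other bases. Strands are assigned forward with probability
`fwd_fraction`. Everything upstream of counts (alignment, duplicate
marking, read-pair overlap) is deliberately outside the abstraction:
the package starts from a per-site allele-count table, which is also
its real-data entry point (`read_counts_tsv()`).

The caller combines exactly four pieces of evidence, each a gate:

1. **Coverage**: depth ≥ `min_depth` (default 50).
2. **Error model**: a likelihood-ratio test of
   H₀: alt ~ Binomial(depth, ε̂) against
   H₁: alt ~ Binomial(depth, MAF̂), where ε̂ is the global sequencing
   error pooled over all sites with allele fraction below
   `maf_ceiling`. The statistic 2(ℓ₁ − ℓ₀) is clamped to 0 when
   MAF̂ ≤ ε̂ (one-sided alternative) and referred to the upper tail of
   χ²₁. Using the *total* miscall rate for a single allele's null is
   deliberately conservative.
3. **Strand bias**: an exact two-sided binomial test of the forward
   alternate count against `fwd_fraction`; artefacts concentrated on
   one strand are filtered at `strand_alpha`.
4. **Allele frequency**: MAF ≥ 3% ("low" stringency) or ≥ 7%
   ("standard"), both inclusive, matching the screen's published
   cut-offs. Both stringencies are carried side by side
   (`passes_low`, `passes_standard`) because real screens inspect the
   low-stringency calls for causal alleles that narrowly miss the
   standard gate.

Variants seen in a mutagenized-but-unselected control pool are
subtracted allele-wise (contig, position, alternate base) before
annotation. After consequence annotation, candidate genes need at least
`min_recurrence = 2` *distinct* protein-altering alleles and are ranked
by hits per kbp of coding sequence. Distinctness matters: pooled
sequencing cannot tell one clone at 10% from two clones sharing an
allele at 20% by count alone, so a shared allele is one hit, and the
carrier multiplicity is reported separately as round(MAF·N).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_clones` | 10 | clones pooled per library |
| `n_resistant` | 8 | clones carrying a causal allele (the screen design recovered causal alleles from 8 of 10 clones) |
| `shared_multiplicity` | 2 | clones sharing the first causal allele |
| `mean_depth` | 150 | mean sequencing depth (×) |
| `seq_error` | 0.001 | per-read miscall probability |
| `per_base_rate` | 1e-5 | background ENU SNVs per bp per clone |
| `min_depth` | 50 | caller coverage gate |
| `maf_low`, `maf_standard` | 0.03, 0.07 | MAF cut-offs |
| `lrt_alpha` | 1e-6 | LRT level; ~Bonferroni for an exome-scale number of tested bases |
| `strand_alpha` | 0.01 | strand-bias rejection level |
| `maf_ceiling` | 0.01 | sites below this fraction feed the error estimate |
| `d1`, `d2` | 5 Å, 8 Å | interface / proximal distance cutoffs |

The background rate deserves a note: the mutagen dose is titrated in
real screens, but the realized per-base load is not published, so it is
a free simulation parameter. The default of 1e-5 per bp on the ~22 kbp
toy genome gives each 10-clone pool a modest handful of background
coding alleles — enough that ranking has something to beat, few enough
that two background hits rarely recur in the same gene, which is the
regime a genome-scale screen with a compact target space operates in.
The ENU spectrum defaults to the classic bias (A:T→T:A and A:T→G:C
weighted 3× over other changes) and is fully overridable; a uniform
spectrum is available for tests.

## What the generator emulates, and what it does not

The generator reproduces the features the analysis actually consumes:
pooled dilution of haploid alleles (linearity MAF ≈ m/N), Poisson
depth, symmetric per-read miscalls split across three bases, strand
assignment, a shared-allele option, optionally uneven pool fractions
(Dirichlet-skewed — real pooling never mixes clones exactly evenly,
which is why a two-clone allele can read 22.6% rather than 20%), and a
matched unselected control pool built from independent clones.

It does **not** emulate read-level reality: alignment and mapping
error, PCR duplicates, overlapping read pairs, base-quality variation,
GC-dependent coverage, indels (discarded upstream in the real pipeline,
out of scope here), or linkage between variants in the same clone
beyond co-occurrence. Passing tests therefore demonstrate the
*statistical* machinery — calibration, thresholds, recurrence logic —
on idealized counts, not robustness to alignment artefacts. On real
data those artefacts must be handled before the count table is built.

## Numerical choices and degenerate inputs

* Coordinates are 1-based, fully closed, everywhere (GFF3/VCF
  convention); the counts TSV and truth files are validated on read.
* Error-only sites emit one record per observed non-reference base,
  and `estimate_global_error()` aggregates evidence per site before
  applying the MAF ceiling. A single "most prominent base" record per
  site would discard multi-base miscalls and, at 150×, the integer
  cut-off (0.01 × 150 = 1.5 reads) would truncate all two-read
  evidence — together biasing the estimate 15–30% low. The estimate is
  clamped below by `error_floor` (1e-6) so a clean lane never yields a
  zero null rate.
* Zero alternate reads give an LRT statistic of 0 and p = 1; a strand
  test with no alternate reads returns p = 1 by contract.
* MAF and depth comparisons are inclusive (≥), matching the published
  "≥ 3%/≥ 7%" phrasing; candidate ties break by raw hit count, then
  gene id, so output order is deterministic.
* Splice sites are the 2 intronic bases flanking each internal CDS
  boundary (canonical donor/acceptor), classified high-impact; the
  window is configurable. Overlapping genes are annotated against all
  models and the most severe consequence is reported.
* Structure distances use heavy atoms only, over *all* residue atoms
  (backbone included): a substitution may act through its side chain,
  but backbone proximity still marks the pocket. Distance cutoffs are
  reported alongside raw distances so any threshold choice can be
  re-examined. Cross-species residue numbering is never guessed: a
  `residue_map()` (offset or explicit pairs) must say how query
  numbering meets the deposit's numbering. PDB text stores 3 decimals,
  so file round-trips are exact to 1e-3 Å; in-memory distances are
  exact to machine precision and invariant under rigid motion.
* All randomness flows through explicit seeds; identical seeds give
  byte-identical artifacts, and each pipeline stage is re-runnable
  from its on-disk intermediates.

## Design choices where the design was open

* **The probabilistic caller.** The four named evidence types
  (coverage, allele frequency, strand bias, global error) are combined
  as conjunctive gates around a binomial LRT. This is the simplest
  model that uses exactly those quantities; nothing beyond them (no
  base qualities, no per-sample priors) is smuggled in.
* **Hits are distinct alleles, not clone-weighted events**, for the
  observability reason above.
* **kbp normalization**: coding-sequence size in kilobases, so the
  ranking statistic reads "protein-altering hits per kbp of CDS".
* **Exit codes** (pipeline): 0 when the planted causal gene ranks
  first, 3 when truth is known but not recovered, ≥1 on errors — so a
  CI job can assert recovery directly.
* **Toy genome strands alternate** (+, −, +, …) so every end-to-end
  run exercises minus-strand annotation.

## Problem sizes used by the test suite

The packaged simulations are sized for single-CPU runs: toy genomes of
20 genes × 999 coding bp (~22 kbp), pools of 10 clones at 150×,
pooled-design checks on 2000 replicate sites, caller calibration on
10⁵ null sites, error-estimate checks on 2×10⁵ deep-site bases, oracle
equivalence on every depth ≤ 200, and 100 (tests) or 50 (acceptance
script) replicate end-to-end screens. These sizes make the Monte-Carlo
bands in the tests (3 standard errors) meaningful while keeping the
full suite in minutes.

## Known limitations

Single transcript per gene; SNVs only (no indels, hence no frameshift
calls, although the impact filter names the class for completeness);
no statistical significance model for recurrence against background
mutation load (the screen's published analysis did not perform one);
no structure download or homology modeling — the PDB file and the
residue numbering reconciliation are the user's responsibility.
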