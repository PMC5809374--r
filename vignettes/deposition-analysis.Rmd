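---
title: "Mapping histone H3 variant deposition from ChIP-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping histone H3 variant deposition from ChIP-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h3varscan)
```

# The problem

Canonical histone H3.1 is deposited during DNA replication and accumulates
in silent, pericentromeric heterochromatin; the replacement variant H3.3 is
deposited throughout the cell cycle and tracks transcription. The two
proteins differ at only a handful of residues — in vascular plants at
mature-protein positions 31, 41, 87 and 90, with Phe41 unique to plant
H3.1 — so single-residue substitutions can redistribute a variant across
the genome. Detecting such redistribution from epitope-tagged ChIP-seq
requires a small set of reusable computations:

1. collapse duplicate reads and call broad enrichment *islands* against a
   mock (untransformed, Col-0) ChIP control;
2. profile control-normalized enrichment along a metagene coordinate,
   stratified by expression quintiles;
3. group peaks of one sample as shared/unique against another sample's
   peaks and summarize expression, chromatin-state, histone-mark and
   housekeeping-gene enrichment over peaks and genes;
4. classify H3 protein sequences as H3.1- or H3.3-like from their
   diagnostic residues.

`h3varscan` implements these stages over `GRanges` containers, plus a
synthetic-data generator that plants each deposition archetype in a
miniature genome so that every stage is testable end to end without any
external download.

# Island calling

Reads (stranded single-end tags, nominally 50 bp) are first collapsed so
that at most one tag is kept per (chromosome, start, strand) — the
literal reading of collapsing reads that map to identical positions. A
flag collapses irrespective of strand instead; the strand-aware default is
the conservative choice since opposite-strand tags at one coordinate are
distinct fragments.

Each tag is then shifted to its fragment midpoint — start + f/2 on the
plus strand, end − 1 − f/2 on minus, with fragment size f = 200 bp — and
counted in non-overlapping windows of w = 200 bp. With N tags on a genome
of L bp the background is Poisson with rate λ = N·w/L per window.

* **Eligibility.** A window with count k is *eligible* when
  P(X ≥ k | λ_s) < 0.2. The 0.2 default is a reimplementation parameter
  (the upstream broad-domain callers keep an analogous internal threshold);
  it is exposed in the API and the CLI.
* **Islands.** Maximal runs of eligible windows in which consecutive
  eligible windows are separated by at most g/w = 1 ineligible window
  (gap size g = 200 bp). The ineligible interior is included in the island
  span but contributes nothing to the score:

  ```
  windows:   E E . E . . E
  islands:  [E E . E]   [E]      (one gap window may be bridged)
  ```

* **Score.** Σ over eligible windows of −ln Poisson pmf(k; λ_s).
* **Significance.** The island's total sample count is tested with a
  Poisson upper tail against the library-size-scaled control count over
  the same span, floored at the control background λ_c·(number of
  windows). The floor prevents p = 0 calls over control deserts; the
  default cut is raw p < 10⁻³. A Benjamini–Hochberg layer is available
  (`fdr = TRUE`) but off by default, matching how such raw thresholds are
  commonly reported. Replicates are concatenated before duplicate
  collapsing (`callpeaks` accepts several `--sample` files).

Underflowing island p-values are floored at the smallest positive double
so that p always lies in (0, 1]. The caller is held to an independent
oracle in the tests: on grids of ≤ 50 windows its spans and scores must
equal an explicit window-by-window enumerator, and `poisson_sf()` must
match direct series summation to 10⁻¹² relative error.

# Metagene profiles

Every gene contributes 60 bins: 20 × 100 bp upstream of the TSS, 20 body
bins of 5% of the gene each, 20 × 100 bp downstream of the TTS. Body-bin
boundaries are `round(i·len/20)` offsets *from the TSS along the
transcription direction*, so a minus-strand gene's bins are the exact
mirror of a plus-strand gene's and the whole profile is invariant under
mirroring the genome (a property test). Body widths always sum exactly to
the gene length. Bins are clipped at chromosome edges and flagged;
clipped-away bins are kept as zero-width placeholders so the matrix stays
rectangular. Genes shorter than 20 bp are skipped with a log message.

Tags are assigned to bins by the same fragment-midpoint rule as the
caller (the assignment rule is a package choice; midpoint assignment is
consistent with the 200 bp fragment size used throughout). Each library
is scaled to reads per million (RPM) and the per-bin value is

log2((s + ε) / (c + ε)),  ε = 1 RPM,

with the mock control c in the denominator. The pseudocount bounds
log-ratios over empty control bins and makes a region empty in both
libraries sit exactly at 0; it is exposed in the configuration. RPM
scaling makes the profile invariant to library duplication factor.

Expression quintiles rank genes by FPKM ascending, break ties by gene id
(deterministic), and split into five equal groups, remainder to the
lowest groups — 28,000 genes give five groups of 5,600. Group curves are
per-quintile means over genes. Genes overlapping each other or
heterochromatin boundaries are *not* excluded.

# Peak and gene summaries

* **Peak–gene association**: a gene is associated with a peak on ≥ 1 bp
  overlap of the gene body (the association rule is a package choice; an
  upstream promoter extension is available as an option). The sweep-line
  join is tested against an all-pairs oracle.
* **Shared/unique grouping**: query peaks overlapping a reference peak by
  ≥ 1 bp form Group 1, the rest Group 2 ("unique"); percentages are
  reported to the nearest integer, as figure legends report them. A
  count-only entry point reproduces the arithmetic from tabulated totals.
* **Mark/state/housekeeping enrichment**: per region,
  log2((numerator + ε)/(denominator + ε)) of RPM-scaled midpoint counts —
  with an H3 ChIP denominator this is the H3-normalized histone-mark
  value averaged per peak/gene for boxplots; with the mock control it is
  deposition enrichment. The statistic is antisymmetric under swapping
  numerator and denominator.
* **Nuclei proportions**: nearest-integer percentages with an exact
  Clopper–Pearson 95% interval (via `binom.test`), e.g.
  `nuclei_proportion(39, 49)` → 80%.

# Residue classification

Queries are globally aligned (Needleman–Wunsch, match 1, mismatch −1, gap
open 5, extend 1; `Biostrings::pairwiseAlignment`) to a canonical mature
H3 reference after stripping a leading initiator methionine from both
sequences. **All numbering is mature-protein numbering** — position 41
means the 41st residue after Met removal, the convention behind names
like H3K9 and H3Y41; the off-by-one from aligning unstripped sequences is
the classic failure mode and is guarded by tests. Queries shorter than
50 aa or below 40% identity to the reference are rejected as not H3-like
(identity gate, a package choice).

Rules are table-driven because the diagnostic positions differ between
kingdoms: plants use 31/41/87/90 (H3.1 = A-F-S-A, H3.3 = T-Y-H-L),
animals 31/87/89/90 (H3.1 = A-S-V-M, H3.3 = S-A-I-G). The text-anchored
plant residues (A/T31, F/Y41, H3.3 H87/L90) are fixed by the biology
described above; the plant H3.1 core residues S87/A90 were filled in from
canonical public Arabidopsis H3.1 sequences. Classification is a majority
vote across positions with per-position votes reported; ties or
majority-unalignable profiles return `ambiguous`, so a single F41Y
substitution flips only the position-41 vote while the 3–1 majority still
calls H3.1. The bundled reference FASTA contains consensus sequences
assembled in-package (marked synthetic in the filename), not database
records; users supply their own FASTA for real species tables.

# The synthetic study system

`synthetic_config()` defaults describe the desk-scale study genome used
throughout the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 2 Mb (1 chromosome) | total genome |
| `n_genes` | 400 | non-overlapping genes, 1–3 kb |
| `het_fraction` | 0.1 (one centered 200 kb block) | pericentromeric heterochromatin |
| `fpkm_meanlog`, `fpkm_sdlog` | 1, 1.5 | log-normal FPKM of euchromatic genes |
| `n_reads` | 2 × 10⁵ per sample | library size |
| `read_length`, `fragment_size` | 50, 200 bp | single-end tags |
| `enrichment_fold` | 8 | heterochromatin enrichment of the H3.1-like law |
| `three_prime_bias` | 0.6 | within-gene 3′ tilt of the H3.3-like law |
| `background_fraction` | 0.3 | nonspecific uniform mass of the H3.3-like law |

Genes inside the heterochromatin block receive FPKM 0; the chromatin
state track is a gene-scale binarization — silent = heterochromatin
blocks, active = euchromatic gene bodies, with featureless intergenic
space unlabeled, mirroring how published state maps enter this kind of
comparison (labeling the whole euchromatic compartment "active" would
make per-state means insensitive to within-compartment redistribution).
The housekeeping list is the 100 top-expressed euchromatic genes.

Reads are emitted as 200 bp fragment *centers* sequenced as the 5′ 50 bp
on a fair-coin strand, so midpoint shifting downstream recovers the
planted position exactly. The four archetypes:

* **control** — centers uniform genome-wide (the mock ChIP);
* **H33_like** — a `background_fraction` of uniform mass, the rest
  allocated to genes ∝ log(FPKM + 1) (log, not raw FPKM, so quintile
  trends are graded rather than dominated by the top genes) with the
  within-gene density linearly tilted 3′;
* **H31_like** — piecewise-constant density: baseline 1, × fold in
  heterochromatin, and gene bodies × (1 + (fold − 1)(1 − r)²) where r is
  the gene's expression percentile rank. Silent genes get the full fold
  and the most expressed genes essentially none, emulating the negative
  correlation between canonical H3.1 occupancy and transcription
  (graded, not binary, so quintile ordering is monotone);
* **mixed** — a fair Bernoulli mixture of the two laws per read,
  emulating a variant that retains heterochromatin deposition while
  gaining transcription-coupled deposition.

Each sample draws from an RNG stream derived from the base seed plus the
sample name, so archetypes are reproducible in any order and independent
replicates (e.g. a second control for a null comparison) come from a
different stream name. Fixed seeds give byte-identical BED outputs, and
exactly `n_reads` reads are always emitted.

`planted_regions()` exposes the generator's ground truth (regions whose
planted density is ≥ `min_fold` × baseline, default 2) — the reference
for planted-signal recovery: at the default configuration the caller
covers the full heterochromatin block and ≲ 2% of called length falls
outside planted regions, while two independent uniform controls yield
< 1% of the genome in significant islands.

**What the generator does not emulate:** sequencing errors, mappability
and GC bias, paired ends, chromatin-fragmentation irregularities, copy
number, or a real genome's repeat structure. Passing planted-signal tests
therefore demonstrates the correctness of the statistics and bookkeeping,
not robustness to real-data artifacts; on real data the usual caveats
about blacklists, input quality and duplicate rates apply.

# Numerical and design choices

* **Coordinates.** Internally everything is a `GRanges` (1-based,
  closed), the Bioconductor convention; BED's 0-based half-open
  coordinates are converted exactly once at the I/O boundary, and the
  conversion is pinned by tests (a 1 bp gene at GFF n..n round-trips to
  BED `n-1 n`). GFF's 1-based inclusive convention coincides with
  GRanges.
* **Tie-breaks.** Quintile ties break by gene id; duplicate collapsing
  keeps the first tag per key and returns coordinate-sorted output;
  all-zero FPKM still defines a grouping (with a warning).
* **Degenerate inputs.** Empty control libraries, expressionless genomes
  under the H3.3-like law, zero-window sizes, infeasible gene packing,
  overlapping bedGraph windows and non-gene GFF features all fail fast
  with informative errors; malformed BED lines report their line number.
* **Determinism.** `run_pipeline()` writes a fixed directory layout
  (`data/`, `peaks/`, `metagene/`, `tables/`, `log.txt`), stamps every
  table with a hash of the configuration, writes no timestamps, and is
  byte-identical across reruns of the same config.
* **Problem sizes.** The test suite exercises the full 2 Mb / 2 × 10⁵
  read configuration for the recovery and trend checks, a 0.4 Mb / 3 ×
  10⁴ read genome for unit-scale properties, and ≤ 50-window grids for
  oracle equivalence; the whole suite runs in a couple of minutes on one
  CPU.

# Limitations

* The island significance model tests each island once against its scaled
  control; it does not reproduce any particular released implementation
  of the published broad-domain callers bit for bit, and the default is a
  raw p cut rather than an FDR (both available).
* Peak–gene association and the promoter window are deliberately simple
  overlap rules; no transcript-model weighting.
* The classifier reads single diagnostic residues off one global
  alignment; it does not attempt phylogenetic placement, and the bundled
  references are consensus constructs intended as alignment anchors.
* Chromatin states and housekeeping lists are user-supplied inputs in
  real analyses; the synthetic track is a binarized stand-in.
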