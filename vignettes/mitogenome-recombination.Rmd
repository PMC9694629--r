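---
title: "Repeat-mediated recombination analysis in multipartite plant mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-mediated recombination analysis in multipartite plant mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The problem

Plant mitochondrial genomes are rarely the single static circle that an
assembly FASTA suggests. Pairs of repeated sequences act as substrates
for homologous recombination, so a population of mitochondria carries a
*mixture* of genome arrangements: one or two dominant ("major", Mac)
circular chromosomes and a cloud of rearranged minor (Mic) conformations.
A repeat pair can do three things to circles, depending on its geometry:

* **direct repeat, both copies on one circle** — recombination splits the
  circle into two smaller circles, one repeat copy each;
* **inverted repeat, one circle** — recombination inverts the run of
  sequence between the copies;
* **direct repeat on two circles** — recombination fuses the circles.

Long reads settle which of these events actually happen and how often.
Around each repeat there are four possible junction sequences: the two
present in the assembly (`C1`, `C2`) and the two produced by exchanging
the flanks (`C3`, `C4`). A long read that covers a repeat copy *and*
anchors into both flanks discriminates among the four. Counting such
spanning reads gives the per-repeat recombination frequency

$$f = 100 \cdot \frac{n_{\mathrm{Mic1}} + n_{\mathrm{Mic2}}}
        {n_{\mathrm{Mac1}} + n_{\mathrm{Mac2}} + n_{\mathrm{Mic1}} + n_{\mathrm{Mic2}}}\,\%$$

i.e. minor-conformation spanning reads over all confidently assigned
spanning reads. mitorecomb implements this workflow end to end —
repeat discovery, junction construction, read classification, frequency
estimation, active-repeat calling, rearrangement prediction — together
with MISA-style microsatellite scanning, detection of plastid-derived
insertions (MTPTs), and a synthetic-data generator that makes every
stage testable against planted truth.

## Pipeline stages and the choices behind them

### Repeat discovery

`find_repeats()` performs seed-and-extend local alignment of the genome
against itself: exact seeds (default word size 7), ungapped X-drop
extension, then banded gapped refinement with blastn-like scoring
(match +1, mismatch −2, gap open −5, gap extend −2) and Karlin–Altschul
E-values computed against the total genome length (default cutoff
1e-6, minimum length 50 bp). Exact score parity with NCBI BLAST is not
promised — the scorer is stated and reproducible instead — and any
analysis that must match a published BLAST table exactly can ingest the
real BLAST output through `parse_hsp_table()` (standard outfmt 6).

Every chromosome is treated as circular. Repeats spanning the origin
are found by scanning the doubled sequence and de-duplicating hits
modulo the chromosome length; a hit (or its mirror image) contained in
a longer overlapping hit is dropped, as are trivial self-alignments.

### Junction conformations

`build_conformations()` extracts, for each repeat copy, the repeat body
plus a flank on each side (default 500 bp, the window used for junction
verification with long reads; assemblies verified at graph level often
use 1,000 bp, and the flag accepts any value). For an inverted repeat,
copy 2's context is first rewritten in the reverse-complement frame so
both copies read the body on the same strand; the recombinant
conformations are then always "switch the downstream flanks". Three
details are deliberate:

* when the two copies differ (identity < 100%), `C3` carries the body of
  copy 1 and `C4` the body of copy 2 — the copy contributing the
  upstream flank — so classification never hinges on the repeat
  interior;
* all four sequences are reported on copy 1's plus-strand frame; for an
  inverted repeat `C1` and `C2` are reverse complements of each other,
  which is exposed as metadata rather than duplicated records;
* the flank is clipped (with a recorded warning) only when a chromosome
  is shorter than the requested window, and warnings are recorded when
  the two copies' windows overlap (junction support becomes ambiguous)
  or the body exceeds `max_span` (default 5,000 bp).

### Read classification

`classify_reads()` aligns each read (both strands) against each
conformation with a seed-located banded overlap alignment (free end
gaps on both sequences; match +1, mismatch −2, gap −2, linear). A
conformation is a *spanning* candidate for a read when the alignment
covers the full repeat body plus at least `min_anchor` bases (default
100) of both flanks, with edit divergence — mismatch plus gap columns
over aligned columns — at most `max_divergence` (default 0.15, sized
for RSII-era PacBio error rates). The best-scoring spanning candidate
wins; equal best scores give `ambiguous`; no candidate gives
`unspanning`. Because divergence is measured over the full alignment
span rather than an anchor-dependent core, raising `min_anchor` only
tightens the coverage requirement: it can never turn an unspanning read
into a spanning one.

Ambiguous reads are excluded from the frequency denominator: the
statistic divides by reads mapped to *found* conformations, which we
read as confidently assigned reads.

### Active-repeat calling

`call_active_repeats()` flags a repeat as recombinationally active when
each minor junction has at least one supporting read, the two minor
junctions together have at least two, and the repeat body is at most
5,000 bp (a repeat longer than the typical span of library inserts
cannot be covered reliably, so its apparent minor support is not
trusted). These thresholds are an explicit heuristic — they reproduce
the distinction between validated and unvalidated repeats in the study
this pipeline models — and all three are arguments.

### Rearrangement topology

`genome_to_molecules()` abstracts each chromosome into a circular run
of inter-repeat segments and repeat-copy markers; `recombine()`
performs the reciprocal exchange at one repeat and yields the split,
inversion or fusion product; `realize_sequence()` turns any predicted
molecule back into sequence. Repeat copies are treated as atomic blocks
(no exchange inside the body): for exact repeats the junction placement
within the body is topologically irrelevant, and for inexact ones it is
fixed at the body's 5' edge. Markers remember the strand on which the
canonical body reads, so repeated recombination composes correctly and
recombining twice at the same exact repeat is the identity (verified as
a property test). De-duplication of enumerated conformations uses a
canonical form: each circle rotated to its lexicographically smallest
signed element string on whichever strand minimises it, sets compared
as multisets.

### SSR scanning

`scan_ssrs()` reports maximal perfect tandem runs of 1–6 bp units with
MISA-style minimum copy numbers (10/5/4/3/3/3 for mono- through
hexanucleotide units). A run whose unit is itself a tandem of a shorter
unit is reported once at the shortest unit; overlapping candidates are
resolved in favour of the longer run, ties to the smaller unit; motifs
are canonicalised to the smallest rotation on the scanned strand with
no strand collapsing (as MISA does). Two departures from MISA are
deliberate and flagged: compound-SSR merging across interruptions is
off by default (a `compound_max_dist` option provides it, 100 bp being
the conventional distance), and chromosomes are scanned in their linear
frame — a run is never extended through the circular origin — for
parity with how MISA sees a FASTA record. Both can change counts
relative to a MISA run.

### MTPT detection

`find_mtpt()` searches the plastome against the mitogenome with the
same alignment engine (word size 7, E-value 1e-6), ignores hits below
100 bp, and applies a reciprocal-best filter: a hit is kept only if it
is the best-scoring hit among those overlapping its mitochondrial
interval *and* among those overlapping its plastid interval. Mito-side
hits that extend the same plastid region colinearly are merged with a
10 bp tolerance (`merge_tol`; fragment counts are sensitive to it).
`summarize_mtpt()` reports the non-redundant mito-side footprint (via
interval union, so overlapping records never double-count) and its
percentage of the mitogenome and plastome. `group_gene_clusters()`
lists plastome genes fully contained in each transfer (`full`) or
partially overlapped (`partial`); cluster members are contiguous along
the plastome by construction. GFF3 and plain data-frame annotations are
accepted.

## The synthetic-data generator

`sim_config()` / `simulate_genome()` / `simulate_reads()` emulate the
data this pipeline targets, with every planted feature recorded as
truth:

* background: i.i.d. bases at 44.5% GC (typical plant mitogenome
  composition), one to three circular chromosomes, default 50 kb +
  15 kb — a scaled-down two-chromosome architecture chosen to keep a
  full analysis at interactive speed;
* repeats: planted by copy-paste with substitutions to hit a target
  identity, reverse-complemented for inverted pairs, placed with
  clearance margins and bounded retries; chromosomes must be at least
  10× the largest feature;
* MTPTs: segments copied from a companion simulated plastome, with
  non-overlapping source loci;
* reads: lognormal lengths (median 9 kb, log-sd 0.5, truncated to
  1–40 kb, approximating a size-selected RSII library while staying
  desk-scale), uniform circular starts, random strand, and a
  substitution:insertion:deletion error mix of 1:5:4 at a total rate of
  10% (PacBio-like);
* determinism: one master seed derives all per-stage generators by
  fixed offsets; identical configurations give byte-identical output.

`simulate_junction_reads()` draws reads guaranteed to span a chosen
repeat's junctions, with the minor conformations weighted by a planted
fraction *p* — the natural instrument for studying estimator recovery
without wasting reads far from the junction. `evaluate_recovery()`
compares estimates against planted fractions using Clopper–Pearson 95%
intervals (via `binom.test`).

What the generator does *not* emulate: chimeric reads and adapters,
quality-score structure, coverage biases, heteroplasmy beyond a
two-component mixture, and nuclear copies of organelle DNA. Passing
tests on synthetic data therefore demonstrate correctness of the
algorithms under the stated error model, not robustness to every
artefact of real sequencing runs.

## Numerical and testing choices

* Reported percentages are rounded half-up to two decimals
  (`round_half_up()`), matching how such tables are printed; a zero
  spanning-read denominator gives `NA` with a warning.
* The test suite cross-checks the read classifier against an exhaustive
  `Biostrings::pairwiseAlignment` oracle, the SSR scanner against a
  brute-force enumerator, and the rearrangement engine against explicit
  string surgery on raw sequences. Problem sizes in the suite — 5–50 kb
  genomes, hundreds of reads per fixture, a 4 × 20-replicate recovery
  sweep at 1,000 spanning reads per replicate — were chosen as the
  smallest scales at which the statistical checks are still sharp.
* The recovery sweep asserts Clopper–Pearson coverage of planted minor
  fractions p ∈ {0.02, 0.05, 0.10, 0.20} in at least 90% of replicates
  per cell.

## Known limitations

* `find_repeats()` is not a BLAST clone; bit-exact reproduction of
  published HSP tables requires feeding the original BLAST output to
  `parse_hsp_table()`.
* Topology operations require repeat copies that do not wrap the
  circular origin (wrapping repeats are still *found* and their
  junctions built; only the molecule algebra refuses them).
* The classifier models a two-component Mac/Mic mixture per repeat; it
  does not attempt probabilistic mixture modelling of conformation
  abundance across repeats, and reads spanning two junctions of the
  same class are credited to the best-scoring one.
* Counts on real accessions depend on the deposited genome and SRA
  reads and are not recomputable offline; the package reproduces the
  printed per-repeat count arithmetic and all qualitative rearrangement
  outcomes, and its statistical behaviour is certified on synthetic
  data.

## A small worked run

```{r worked, eval = FALSE}
cfg <- sim_config(seed = 7, chrom_lengths = c(MC1 = 50000),
                  repeats = tibble::tibble(length = 300, identity = 100,
                                           orientation = "direct",
                                           inter = FALSE),
                  error_rate = 0.10)
sim <- simulate_genome(cfg)
rp  <- sim$truth$repeats[1, ]
js  <- build_conformations(sim$genome, rp, flank = 500)
jr  <- simulate_junction_reads(sim, rp, p = 0.10, n = 500)
cnt <- count_support(jr$reads, js)
recombination_frequency(cnt)
# with seed 7: mac1 = 204, mac2 = 236, mic1 = 28, mic2 = 32, no ambiguous
# or unspanning reads, frequency 12.00% — the Clopper-Pearson 95% interval
# of 60/500 (9.3-15.2%) covers the planted p = 0.10
```
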