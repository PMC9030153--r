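---
title: "Methods: circular-enrichment mtDNA heteroplasmy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular-enrichment mtDNA heteroplasmy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseekr)
```

## The problem

Human mitochondrial DNA (mtDNA) is a 16,569-bp circular genome present in
hundreds to thousands of copies per cell. A sample can therefore carry a
*mixture* of wild-type and mutant genomes — heteroplasmy — quantified as the
percent of sequencing reads carrying a variant allele. Two obstacles make
low-level heteroplasmy hard to measure from whole-cell DNA: nuclear copies of
mtDNA-like sequence (NUMTs) masquerade as mitochondrial reads, and sequencing
error floods the low-frequency range. Circular-enrichment protocols address
the first obstacle biochemically: exonuclease V degrades linear
double-stranded DNA from both ends, so linear nuclear fragments (including
NUMT carriers) are destroyed while circular mtDNA survives. The second
obstacle is addressed statistically in the caller, by demanding multiple
independent (non-clonal) observations of an allele.

`mseekr` implements this analysis end to end: a circular reference model
with gene map and the vertebrate mitochondrial genetic code; a read
simulator with complete truth tables; the variant caller; somatic-versus-
germline classification of matched peri-normal/tumor pairs; cohort-level
mutation-spectrum and pooled-heteroplasmy summaries; and quantitation of
Southern-blot lane profiles for copy-number and catenane analysis.

## The bundled reference is synthetic

The package needs a concrete sequence to translate, annotate and simulate
against. The bundled FASTA (`synthetic_rCRS.fasta`) is a **synthetic
construct**, not the human rCRS sequence: it reproduces the rCRS at the
structural level — 16,569 bp; the authentic coordinates, strands and overlap
structure of all 37 genes (13 protein, 22 tRNA, 2 rRNA) plus named
non-coding stretches; incomplete stop codons completed by polyadenylation;
the ATP8/ATP6 and ND4L/ND4 dicistronic overlaps with both frames stop-free —
and carries engineered codons at every position the worked examples touch
(so, e.g., position 6481 is the second base of COX1 codon 193 = GTA, and
T6481C encodes V193A; ND5 codon 361 is GGA, so G13417A creates the AGA stop
and a 360-residue product against the 603-residue wild type; positions
302–315 carry the homopolymeric ACCCCCCCTCCCCC motif; position 5899 ends a
run of five Cs in the NC5 non-coding gap). Filler bases elsewhere are random
under a fixed seed, and `synthesize_reference()` regenerates the file
deterministically. Every conclusion the package draws from this reference is
structural (coordinates, codon arithmetic, gene content), never a claim
about the human filler sequence.

## The caller

Reads pass four stages.

1. **Quality filter.** A read is discarded iff it contains a run of more
   than 10 consecutive bases with phred quality below 20 (both numbers are
   arguments). A run of exactly 10 is kept.
2. **Circular mapping.** Exact-or-near-exact seed-and-extend over the
   doubled genome string, so reads spanning the origin need no special
   casing: 16-mer seeds at read offsets 0/16/32 propose a start, ungapped
   extension accepts up to `max_mismatch` (default 2) mismatches, and both
   orientations are tried. Reads that fail ungapped extension but have a
   seed hit are rescued by a split-read alignment that allows one short
   (1–2 base) internal indel plus substitutions, minimizing prefix +
   shifted-suffix mismatches over all split points; within homopolymers the
   3'-most split is chosen, matching the notation that anchors an inserted
   base at the run's 3' end (C5899CC). Reads matching the repeat-decoy
   library are labeled rather than dropped; so are unmapped reads.
3. **Clonal collapsing.** Reads identical in start, strand and sequence are
   treated as clonal copies of one original molecule and counted once,
   whatever their multiplicity.
4. **Thresholded calling.** Every observed non-reference allele is emitted
   with a filter status; PASS requires at least 3 non-clonal supporting
   reads, non-clonal site coverage of at least 10, minority-strand fraction
   (skew) of the support of at least 0.1, and a position outside the
   302–315 blacklist.

Design choices the procedure leaves open, resolved here:

* **Skew.** "Variants occurring on reads of one strand (skew greater than
  0.1)" is implemented as: skew = minority-strand fraction of supporting
  reads; exclude when it is *below* 0.1 (i.e. more than 90% of support on
  one strand). This is the only reading under which one-sided support is
  excluded and balanced support retained. The threshold is an argument.
* **Percent-variant.** The primary value (`vaf_plus`) is the plus-strand
  convention — supporting plus-strand reads over plus-strand coverage — the
  convention in which the per-variant percentages of the source tables are
  printed; `vaf_both` (both strands) is always reported alongside.
* **Coverage.** The coverage gate applies to *non-clonal* coverage, since
  only non-clonal reads count toward calling; the clonal-inclusive depth is
  recoverable from the multiplicity map.
* **Blacklist.** Calls at 302–315 are emitted with status `blacklist` and
  can never PASS; the region's homopolymeric structure produces artefactual
  calls, the reason the C315CC insertion is conventionally not analyzed.
* **Multi-allelic sites.** Each alternate allele is evaluated independently;
  no per-site cap.

**Error arithmetic.** With per-base error `p` (1e-3 at Q30), the chance of
`n` independent reads showing the same erroneous allele is `p^n`
(`coincident_error_probability()`): about 1e-6 for two reads and 1e-9 for
three — the rationale for the support threshold. Note that this is a
per-read-set probability; across ~16,569 positions and ~3 alternate alleles
at coverages of several hundred, a handful of coincident-error alleles do
reach 3 supporting reads. These appear as PASS calls at fractions of a
percent and are trivially separable from heteroplasmies at the 10–90% scale;
the classifier exposes an optional `min_somatic_vaf` floor for users who
want them rerouted, off by default to keep the operational rule faithful.

## The simulator

`build_molecule_population()` describes a sample as molecule species:
circular mtDNA haplotypes at stated fractions, plus linear nuclear species —
NUMT fragments (a contiguous mtDNA segment of 500–5,000 bp embedded in
300 bp of random nuclear background per side) and repeat decoys (fixed
pseudo-random LINE/SINE stand-ins from `synthetic_repeat_library()`).
`apply_exov()` destroys each linear molecule independently with the stated
efficiency. `simulate_reads()` samples read starts uniformly around circles
(wrapping the origin) or along fragments, perturbs bases with a uniform
substitution error at the phred-implied rate (no indel errors: substitution
error dominates the platform this emulates), emits constant phred+33
quality strings consistent with that rate, duplicates reads geometrically
at the clonal rate, and records full per-read provenance.

Two generator choices deserve explanation:

* **Read-length jitter** (default: lengths uniform on 110–150). Real
  libraries have variable insert sizes and trimming, so byte-identical reads
  are almost surely amplification duplicates. A fixed-length simulator
  violates that: at depths of several hundred, distinct molecules collide on
  (start, strand) and identical-read collapsing then *biases* the majority
  allele downward (both alleles lose duplicates, but the more abundant
  allele loses more). Jitter restores the property that identical reads are
  clonal, which is the premise of the collapsing rule.
* **Independent-site mixtures.** Tumor-only variant fractions (e.g. five
  variants at 26–71%) sum to more than 1, so they cannot sit on disjoint
  haplotypes. `make_matched_pair_dataset()` realizes them as an
  independent-site mixture: all 2^k subsets of the k tumor-only variants
  become explicit haplotypes with product weights, which reproduces every
  marginal fraction exactly without asserting an unknown linkage structure.

What the generator does *not* emulate: platform-specific error spectra,
PCR chimeras, mapping-quality structure, a real nuclear genome, or real
repeat-element sequence. Tests that pass on these simulations therefore
validate the pipeline's logic and statistics, not its robustness to every
artefact of real libraries.

## Classification and cohort statistics

A variant *present* in a sample means a PASS call. Present in tumor only:
**somatic**; in both samples and in the haplogroup table: **germline**; in
both but absent from the table: **shared_possibly_acquired**; in normal
only: **normal_specific**. Haplogroup membership means any entry in the
user-supplied frequency table, at any frequency (observed branch
frequencies for true inherited variants span roughly 1.3–99.7%, so no
frequency cutoff is defensible). Heteroplasmy status: heteroplasmic at
<= 92% variant, nearly homoplasmic above 92% and below 100%, homoplasmic at
100%.

Cohort summaries follow the printed conventions: percent heteroplasmy is
`variant/(variant+WT) x 100`; the read-count filter for tabulated
reanalysis retains rows with `max(tumor variant, tumor WT) > 100` (the
"variant or WT" wording read literally as *either*; a `require_both` switch
gives the stricter reading), normal WT > 100, and residual normal
heteroplasmy < 0.4%. Mutation spectra are tallied in L-strand orientation
over the 12 substitution classes, with indels apart; the transition percent
uses all variants (substitutions plus indels) as its denominator, the
convention under which 8 transitions among 10 variants is 80%. Means are
printed to one decimal and pooled percents rounded half-up to integers
(10/16 = 62.5% prints as 63%).

## Densitometry

Lane profiles are 1-D intensity traces extracted from blot images by the
usual manual lane selection; the computational content — integration and
normalization — is what this module owns. Bands are integrated by
trapezoidal rule, optionally minus a linear baseline drawn between the
window endpoints. Copy number is the mtDNA/nDNA band ratio normalized to a
reference lane (= 100%). Lane loading is summarized as percent-of-total
with its %CV. Catenane content is the catenane-window signal as a percent
of whole-lane signal, compared between normal and tumor groups by fold
change and a two-sided equal-variance t-test (significance at p < 0.05);
the catenane window is user input per lane, as on a real blot. All
quantities are invariant to a global intensity scale.

## Numerical notes and limitations

* Insertion calls near read ends are intrinsically under-counted: a read
  whose inserted base lies within a few bases of its end (or inside the
  homopolymer run it extends) aligns equally well ungapped, so it
  contributes coverage but not insertion support. At 150-bp reads this
  depresses a single-base-insertion fraction by roughly a fifth of its
  value; substitution fractions are unaffected.
* The mapper prefers ungapped interpretations within its mismatch budget,
  like standard aligners; it is exact/near-exact by design and is validated
  against simulator truth, not intended for divergent real-world reads.
* Default test problem sizes were chosen to exercise the statistics at
  realistic scale while staying desk-sized: matched-pair recovery runs at
  mean depth 600 (the printed per-site coverages span 424–794) with
  150-bp reads over 10 seeds; targeted-depth checks use windowed
  simulation at site coverage up to 10,000.
* All generators are bit-reproducible under a fixed seed, and every
  stochastic test fixes one.
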