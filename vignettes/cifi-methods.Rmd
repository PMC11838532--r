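---
title: "Methods and design notes: multi-way 3C contacts from concatemer reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cifi)
```

This vignette is the package's own account of what it computes, which
modelling and numerical choices were open, and what its green tests do and
do not establish.

## The data model

A 3C library sequenced as long reads produces *concatemers*: each read is a
chain of restriction fragments ("monomers") joined at ligation junctions.
Because ligation preferentially joins loci that were spatially proximal, a
read with $n$ monomers encodes an $n$-way contact, which downstream Hi-C
tooling consumes as all $\binom{n}{2}$ unordered pairs. Everything in this
package flows from three objects:

* a **fragment map** — the reference genome cut at every enzyme site,
  0-based half-open, tiling each chromosome exactly;
* **segments/monomers** — pieces of one read produced by in-silico digestion,
  each later anchored on the reference by one selected alignment;
* **contact pairs** — unordered monomer pairs of one read, mate-normalized to
  the upper triangle of (chromosome order, position).

Coordinates are 0-based half-open internally and converted only at
serialization boundaries (4DN pairs and BAM are 1-based on disk). This keeps
interval arithmetic free of off-by-one special cases.

## Digestion

Cut positions are motif start + cut offset on the top strand; the built-ins
are DpnII (GATC+0), HindIII (AAGCTT+1) and NlaIII (CATG+4). A ligation
junction of a sticky-end product reconstitutes exactly one recognition site,
so one cut per motif occurrence is the correct splitting rule and no
junction detection is attempted. Matching is case-insensitive (soft masking
is annotation, not sequence) and `N` never satisfies a motif position.
Custom enzymes may use IUPAC codes; built-ins are matched literally.

Segments shorter than `min_segment_length` (default 20 bp — below any
mappable length, chosen once; the source protocols state no floor) are
flagged rather than dropped, so the concatenation-reassembly invariant stays
checkable on every read while pairing ignores them. Ordinals count all
segments, filtered or not, so segment identity is stable across filters.

## Alignment selection and pairing

One alignment is kept per (read, ordinal): primary records always beat
secondary/supplementary ones, then longest reference span, then smallest
(chromosome, start) — a deterministic total order. The MAPQ floor (default
1, the headline stratum of repeat-resolution comparisons) applies *before*
pair expansion, so a discarded monomer contributes no pairs.

The monomer anchor is its 5′-most reference coordinate, matching short-read
Hi-C convention so concatemer-derived and conventional matrices are directly
comparable. Duplicate flagging is pair-level: across *different* reads,
byte-identical (chrom1, pos1, strand1, chrom2, pos2, strand2) records keep
only the first (reads sort lexicographically, so an original precedes its
`_dup` copy). Pairs of one read never flag each other. On toy-sized genomes
a few percent of *coincidental* cross-read repeats are flagged on top of
true copies; at realistic genome sizes this excess is well below 1 % (the
test suite demonstrates both regimes).

Counters are reported at every stage (alignments seen, segments aligned,
selected, below-MAPQ; pairs with and without duplicates), so totals under
any combination of MAPQ filtering and deduplication can be reconstructed —
the upstream description leaves that combination unstated.

## Matrices and balancing

Binning is exact counting: each non-duplicate pair increments one upper
triangle cell, so the matrix total equals the pair count at every
resolution, and aggregating a fine matrix 50× equals direct coarse binning
integer-for-integer (both are tested).

Balancing is the Knight–Ruiz inner–outer Newton iteration (conjugate
gradient inner solve with the canonical $\delta = 0.1$, $\Delta = 3$
safeguards, forcing-sequence $\eta$ updates), returning weights $w$ with
$w_i M_{ij} w_j$ having unit row sums within `tol` (default $10^{-6}$,
`max_iter` 300). Bins with zero marginal, or marginal below the 2nd
percentile of nonzero marginals, are masked first and receive `NA` weights
(the sources are silent on masking; the choice is recorded in the matrix
metadata). If Newton fails, a damped symmetric Sinkhorn fallback runs and
the normalization tag records `"KR-sinkhorn"`; if both fail the raw matrix
is left untouched and an error is raised. The doubly stochastic scaling of a
symmetric positive matrix is unique, which is why an independent
high-precision Sinkhorn iteration serves as the test oracle.

Matrix correlation is Pearson on `log1p` counts over the union of nonzero
cells, optionally restricted to a bin mask (e.g. "unique" vs
"SD/centromere" bins) and computable on raw or balanced counts — whether
published map correlations used raw or normalized counts is unstated, so
both are exposed.

## QC statistics

*Distance decay.* Cis-pair distances $|pos_2-pos_1|$ are histogrammed in
log10-spaced bins from `min_dist` (100 bp) to $10^{8.5}$ bp and normalized
by bin width, estimating $P(s)$. The decay exponent is an OLS slope of
$\log_{10}$ frequency on $\log_{10}$ distance over non-empty bins in a stated
fit range; on finite simulated chromosomes the fit range should stay within
about a tenth of the chromosome length, beyond which boundary truncation
biases the tail.

*MAPQ by class.* A segment belongs to an annotation class when its selected
alignment overlaps a class interval by ≥ 1 bp; classes are analyzed
independently, so a segment may count in several. For thresholds
{1, 10, 20, 30, 60} the fraction with MAPQ ≥ t is reported out of aligned
segments in the class (the raw numerator and denominator are both returned,
so other denominator conventions can be formed); zero-overlap classes are
absent rather than 0, keeping "no data" distinct from "nothing mapped".

*Windowed coverage.* Mean per-base depth in 5 kbp windows stepping 4 kbp —
"1 kbp overlap between windows" read as step = window − overlap, the only
consistent reading. Tracks are normalized to genome-wide mean 1 and smoothed
with a centered rolling mean over 25 windows before differencing; the
original workflow used a GAM here, but the comparison it supports is
qualitative, so smoother identity is not load-bearing.

## TAD calling and concordance

The boundary signal at inter-bin boundary $b$ is the mean contact between
the $w$ bins upstream and $w$ bins downstream (windows truncated at ends;
$w$ defaults to 5 bins). Boundaries are local minima passing a depth filter,
with minima closer than $w$ bins merged to the deeper one; domains are the
intervals between boundaries, so the partition covers every bin and masked
bins are bridged into surrounding domains.

**Depth filter (a deliberate design deviation).** The original plan was
"deeper than median − 1·MAD". That filter cannot work: roughly a quarter of
any signal lies below it, so chromosomes with few true boundaries always
acquire spurious ones — planted 2-domain chromosomes were consistently
called with 4–5 domains. The filter shipped is median − 3·MAD (unscaled
MAD, `depth = 3`, configurable): true boundary dips at ≥ 4:1 contact
contrast sit many MADs deep, while noise minima rarely exceed two. With it,
planted partitions of 2–6 domains are recovered exactly with boundaries
within ±1 bin over 20 seeds. Calling is done on balanced matrices by
default: raw matrices carry coverage edge artifacts that dip the signal
about $w$ bins from chromosome ends.

MoC between partitions follows the cited definition: 1 when both partitions
are a single domain, else
$\big(\sum_{ij} |P_i \cap Q_j|^2/(|P_i||Q_j|) - 1\big)\big/\big(\sqrt{N_P N_Q} - 1\big)$,
sizes in bins; identical partitions give exactly 1 and the degenerate
whole-vs-singletons case gives exactly 0 (values are clamped against
$10^{-16}$-scale float noise at the ends). Published concordance was
reported "across chromosome 1" in one place and "chromosomes 1 and 2" in
another; the API takes an explicit chromosome list rather than guessing.

## The simulator: what it emulates, and what it does not

The generator is a stated world, not a tuning knob:

* **genome** — i.i.d. random sequence at GC 0.41 (human-like); optional
  planted segmental duplication copied at a stated identity (98 % in tests,
  the conventional SD98 threshold), with monomers inside either copy given
  MAPQ 0 to model multi-mapping ambiguity.
* **segments per read** — 1 + negative binomial with dispersion 1.5,
  parameterized so the median hits the target (17 by default, DpnII-like;
  2 emulates a 6-cutter library). Only the medians are published; the shape
  is a free choice recorded here and in the config.
* **contacts** — each read has an anchor fragment; every other monomer is
  trans with probability $f_t$ (default 0.25) or cis with partner distance
  $s$ between fragment midpoints drawn $\propto s^{-\alpha}$ (default
  $\alpha = 1$), optionally multiplied by 4 for same-domain partners when
  domains are planted. Partner sampling is per-fragment, matching the
  fragment-level resolution of proximity ligation.
* **reads** — monomer cores concatenated with the full recognition motif
  reconstituted once per junction, plus the motif's split halves at the read
  ends. The built-in motifs are palindromic and borderless (no proper prefix
  equals a suffix), which guarantees — not just makes likely — that a
  simulated read contains cut sites exactly at its junctions: digestion
  recovers truth boundaries byte-exactly, with no rejection sampling.
  Reverse-strand monomers align to the fragment interval shifted by
  $|m| - 2c$ (the cut-offset shift of a reverse-complemented ligation
  product), and the emitted oracle alignments carry that shift.
* **duplicates** — a stated fraction of reads (default 1.8 %, a published
  PCR-duplicate rate) copied verbatim under new ids, truth-linked.
* **not modelled** — sequencing errors (HiFi QV ≈ 38 is error-free at this
  scale), partial digestion, star activity, methylation sensitivity,
  haplotypes. Alignment itself is out of scope: the oracle TSV plays the
  role of a perfect aligner, and the BAM reader ingests real alignments when
  you have them.

Consequently a green simulation test establishes that the *processing* is
correct (splitting, selection, expansion, binning, balancing, calling), not
that any particular biological dataset will reproduce published values —
those require the original sequencing data.

One measurement subtlety is worth spelling out. Expanding all pairs mixes
anchor–partner contacts, whose distances follow the sampled $s^{-\alpha}$
law exactly, with partner–partner contacts, whose distances are
sums/differences of two independent draws and follow a flatter law (−0.82
observed vs −1.02 for anchor pairs at $\alpha = 1$). Parameter-recovery
tests therefore measure the exponent and the trans fraction on
anchor-involving pairs, which the truth table marks (`is_anchor`); the
trans fraction of anchor pairs is an exact Bernoulli($f_t$) sample, giving a
clean $3\sigma$ binomial criterion.

## Numerical and degenerate-input choices

* Lower-median convention for count statistics (even-sized samples return an
  observed value).
* `kr_balance` convergence is measured on the squared residual of row sums;
  non-convergence raises rather than returning half-balanced weights.
* `expand_pairs` of 0 or 1 monomers is an empty table, not an error; an
  empty pair set serializes to a header-only pairs file that reads back.
* Chromosome order everywhere is genome (FASTA/chromsize header) order,
  never lexicographic; mate normalization and pair sorting depend on it.
* Chromosomes shorter than $2w$ bins yield one whole-chromosome domain.
* The FASTQ writer is package-local because the Bioconductor writer aborts
  on records longer than its internal buffer (~20 kb), which concatemer
  reads routinely exceed.

## Known limitations

* The TAD caller is a deterministic stand-in for the full statistical
  machinery of window-signal callers; it is designed for reproducible map
  comparison, not for publication-grade boundary catalogs.
* Pair-level deduplication cannot distinguish a PCR copy from a biological
  recurrence of the same fragment pair; on small genomes the coincidence
  rate is visible (a few percent), though negligible at mammalian scale.
* `ingest_alignments` keeps one placement per segment; split/chimeric
  alignments within a segment are not rescued, and no walk-filtering of
  adjacent-in-read monomers is applied (none is applied upstream either).
* The `.hic` binary format and ICE/VC normalization variants are out of
  scope; the triplet-text container plus chromsizes is the interchange.
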