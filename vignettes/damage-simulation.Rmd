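---
title: "Simulating post-mortem damage and its impact on variant calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating post-mortem damage and its impact on variant calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeovar)
```

## The question the pipeline answers

Ancient DNA is short, chemically damaged, and usually sequenced shallowly.
All three properties interfere with the standard short-read workflow — map
reads to a reference, call SNPs and indels from pileups — and their effects
are hard to separate in real data, where the true genotype is unknown.
palaeovar takes the simulation route: it synthesizes a reference genome and
a divergent diploid "sample" whose variants are known exactly, degrades
reads from that sample the way post-mortem chemistry degrades ancient DNA,
runs a complete mapping-and-calling pipeline, and scores the calls against
the recorded truth. Because every stage is parameterized, the effect of GC
content, reference divergence, read length, damage intensity and coverage
depth on variant recovery can be measured factorially.

## The genome model

`simulate_pair()` evolves sequences along the tree

```
(reference:1x, (chromosome1:0.5x, chromosome2:0.5x):0.5x)
```

so the diploid sample is approximated by a bifurcation halfway along its
divergence from the reference lineage. Substitutions follow the HKY model
(transitions at `kappa = 2` times the transversion rate) with four
discrete-gamma rate categories (shape 1, quantile-midpoint discretization)
and 10% invariant sites; base frequencies place the configured GC content
symmetrically on G and C. Substitutions are applied per branch with
closed-form transition probabilities, so multiple hits within a branch
collapse — which is also what an alignment of the endpoint sequences would
show. Events on the shared 1.5x path between the reference and the
chromosome ancestor are homozygous; events on a 0.5x terminal branch are
heterozygous, giving an expected hom:het event ratio of 3:2.

Indels are drawn with lengths from a truncated power law
(P(k) proportional to k^-1.7, k <= 5); the realized mean length is about
1.72 bp. Indel events are placed uniformly, with a minimum spacing of
`2*max_len + 2` bp enforced by resampling so events never overlap and the
truth catalog stays replayable; the event count is set so indel-affected
positions match SNP-affected positions in expectation. Insertions placed on
the internal branch do not accumulate further substitutions on the terminal
branches — a simplification that affects under 2% of inserted bases at the
divergences used here. Truth indel positions are recorded where the events
occurred; calls are left-aligned by the mapper, and the +-3 bp matching
window in evaluation absorbs the residual placement ambiguity, which is the
same reason the original analysis needed that window between its alignment
tools.

The tree unit `x` is not taken on faith: `calibrate_branch_scale()` solves
for the value whose *expected* variant-position density (computed exactly
from the transition matrices, per rate category) hits the target for the
divergence level — 2.6 variant positions/kb for "low" (a same-species
reference) or 29/kb for "high" (a congeneric reference). Tests verify the
realized density lands within a few percent.

## Reads, trimming, and damage

Raw reads are 100 bp single-end fragments drawn uniformly from both strands
of both chromosomes. Base-call errors are uniform substitutions at constant
quality (default Q35, i.e. 3.2e-4 per base); this forgoes machine-specific
error profiles in exchange for an exact error ledger.

Trimming reproduces fragment-size distributions of highly degraded DNA:
15% of reads sit exactly at the mean length (40, 60 or 80 bp) and each 1 bp
step away multiplies the probability by 0.75, truncated at +-10 bp and
renormalized. Trimming keeps the 5' end, since Illumina reads are sequenced
5'→3'.

Damage has two components:

* **Fragmentation bias.** A trimmed fragment is accepted with probability
  `0.5 * w5(b5) * w3(b3) / max(w5) / max(w3)`, where `b5` is the genomic
  base immediately 5' of the fragment start on its source strand and `b3`
  the base immediately 3' of its end. The weight tables encode purine
  preference 5' of breakpoints (G over A by ~2x) and the pyrimidine mirror
  at 3' ends: low damage `{G 1.2, A 1.1, T 0.9, C 0.8}`, high damage
  `{G 1.6, A 1.3, T 0.7, C 0.4}`. The full bordering-nucleotide frequency
  table of the original study is not public; these tables are
  reverse-engineered from its reported composition shifts (+20%/+10% at low
  damage, +60%/+30% at high) and are config-overridable. Because only the
  maximum-normalized ratio enters the acceptance probability, the tables
  shape composition without changing the overall yield mechanism.

* **Terminal deamination.** Scanning from the 5' end, a C at offset i flips
  to T with probability `p0 * 0.75^i` (p0 = 0.12 low, 0.40 high), until the
  probability drops below 0.01 — which is why damage reaches exactly 9
  positions per end at low damage and 13 at high. The 3' scan flips G to A
  symmetrically. Both tracks run independently, so a 30 bp read can be hit
  from both ends. Damage applies to the read base as sequenced (after any
  sequencing error), matching a workflow that damages simulator output.

`simulate_read_pool()` fuses draw-trim-accept-error-damage into one pass
that never materializes rejected fragments; it is distributionally
identical to composing the individual operations, which remain exported and
are tested both separately and against the fused path. Coverage depth is
accounted pre-mapping, as drawn read bases over the haploid reference
length — the only seed-independent reading of depth targets.

## Mapping and calling

The built-in mapper indexes exact reference 13-mers and maps each read by
seed-and-extend: seed hits every 2 bp along both strands, hit diagonals
clustered within the band width, and each candidate locus scored by banded
(band 6, covering the 5 bp maximum indel) semi-global edit-distance
alignment. A read maps only if its best alignment has edit distance at most
`ceiling(0.06 * length)` and no other locus ties it — ties mean the read
would multi-map and are discarded, as a zero-MAPQ filter would. Indels are
left-aligned; among equal-score alignments one ending in a match/mismatch
column is preferred over one ending in an indel, so terminal damage is
expressed as a mismatch rather than a spurious terminal insertion. The
mapper is validated against an exhaustive unbanded all-positions aligner on
small references.

The caller accumulates per-column base observations and computes diploid
genotype likelihoods over {hom-ref, het, hom-alt} with per-base error from
the base quality (capped at Phred 40), a prior of theta = 1e-3 on het and
theta/2 on hom-alt sites, and QUAL equal to the Phred-scaled posterior of
hom-ref (capped at 300). The prior matters at the depths this study cares
about: with a flat prior a single read would yield QUAL ~35 hom-alt calls
that pass the QUAL >= 20 filter, and sub-1x accuracy would collapse under
damage artifacts. Indels are genotyped from supporting vs spanning read
counts with the same machinery; their error term (`eps_indel = 0.05`) is
dominated by alignment ambiguity — reads whose ends fall at or inside an
event align without the indel op — not by sequencing error, and a smaller
value demonstrably inverts the hom:het recovery trend by flipping
homozygous indels to het.

Calls are filtered to QUAL >= 20 and depth 1-30. The grid driver also
applies strand-bias (Fisher exact) and end-distance-bias (Welch t on
distance to the nearest read end) filters at p < 1e-4, skipped below two
observations per allele — the defaults of the classic pileup variant-filter
stage, which an emulation of that pipeline contract should include. Both
are exposed via `filter_pileup_bias()` and can be disabled.

## Evaluation rules

Variants are scored inside a 500 bp edge margin. A SNP call is correct only
if position and alternate base both match; SNPs within 5 bp of any indel
position (truth or called) are excluded from both sets. Heterozygous
positions are scored at the allele level: a hom record contributes two
allele calls, a het one, so a truth-het called hom yields one correct and
one spurious call. Indels match truth one-to-one within +-3 bp,
position-only (length and sequence are not compared; that strictness is
configurable); the matcher processes calls in position order and takes the
leftmost unmatched truth event in the window, which is the maximum-
cardinality assignment for this convex structure and is tested against an
exhaustive assignment oracle. Zero calls of a kind yield accuracy NA, never
0. The hom:het ratio of ratios divides the hom:het ratio among correctly
called variants by the same ratio in the truth; 1 means unbiased zygosity
recovery.

## The factorial experiment

`run_grid()` crosses 3 GC contents x 2 divergences x 3 replicate genome
pairs x 3 read lengths x 3 damage levels x 7 depths (0.1-16x): 378
triplicate-averaged cells, 1134 read pools. Per treatment one accepted pool
is generated at just over 16x and mapped once; each depth subsamples that
pool — equivalent to subsampling first, because mapping is per-read and
deterministic, and ~1.8x cheaper. Every stage seeds from
`derive_seed(master, stage, indices...)`, so single cells can be reproduced
in isolation. Replicate averages (with SDs) feed `regress_metrics()` (OLS
on GC%, read length, damage coded 1/2/3, and depth or log-depth, run per
divergence level) and `compare_slopes()` (ANCOVA-style interaction test
between divergence levels).

## Problem sizes, and what reduced scale does and does not show

The published study used 10,001,000 bp genomes; this package's experiments
default to 1 Mbp, the test suite exercises 4 kb-200 kb genomes, and the
shipped acceptance script runs the full factorial at 250 kb with triplicate
pairs — sizes chosen so a complete run is a desk job rather than a cluster
job. Scale reduction leaves per-position statistics (damage rates,
composition shifts, trim distribution, per-cell accuracy and completeness)
unbiased and only widens their sampling error: a 250 kb low-divergence pair
carries ~650 variant positions, so a 16x completeness estimate averaged
over 27 cells has a standard error well under one percentage point. What
reduced scale cannot show is anything driven by genome-scale repeat
structure; since sequences here are i.i.d. draws, reference uniqueness is
near-total at every scale, which is a model property rather than a scale
artifact (see limitations).

## Known limitations

* The error model is uniform and the quality constant; ART-style position-
  dependent error profiles would lower mapped fractions for longer reads
  more sharply than this model does.
* The mapper's edit-distance contract (6% of read length, free gaps within
  the band) is more permissive than the historical BWA-aln configuration it
  emulates, and the genotyper recovers heterozygotes efficiently at 16x
  where consensus-era callers did not. Both raise variant completeness at
  high divergence and high depth relative to the numbers the original
  BWA/SAMtools stack produced; mappability and completeness results should
  be read as properties of this pipeline, not of that legacy stack.
* Simulated genomes have no repeat structure, so multi-mapping and its
  interaction with damage are essentially absent.
* Damage is deamination-shaped substitution only: no nicks, abasic sites,
  single-stranded overhangs, or UDG-treatment chemistry.

## A worked example

```{r example, eval = FALSE}
library(palaeovar)

cfg <- calibrate_branch_scale(genome_sim_config(
  length_bp = 200000L, gc_content = 0.5, divergence_level = "low",
  seed = 7))
pair <- simulate_pair(cfg)

set.seed(derive_seed(7, "pool"))
pool <- simulate_read_pool(pair, trim_distribution(60),
                           damage_config("low"),
                           target_bases = 17 * nchar(pair$reference))
mapped <- map_reads(build_index(pair), pool)
calls <- filter_pileup_bias(filter_calls(pileup_and_call(mapped, pair)))
evaluate_pool(calls, pair$truth, nchar(pair$reference))

misincorporation_by_position(
  structure(mapped, damage_ledger = attr(pool, "damage_ledger")), pair)
```
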