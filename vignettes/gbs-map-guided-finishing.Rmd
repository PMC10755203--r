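---
title: "Genetic-map-guided genome finishing from GBS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-map-guided genome finishing from GBS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsmapr)
library(dplyr)
```

# The problem

A long-read draft assembly of a plant genome arrives as hundreds of contigs
of unknown chromosomal origin, order and orientation, some of them chimeric
(joining sequence from two unrelated regions). Given two inbred parental
lines and an F2 intercross population genotyped by sequencing (GBS), a
genetic linkage map provides everything needed to finish the assembly:
linkage groups identify chromosomes, marker order along the map orders and
orients contigs, and coordinated genotype switches inside a contig expose
misjoins. `gbsmapr` implements that whole path — from raw parental genomes
and multiplexed GBS reads to chromosome-scale pseudomolecules with AGP
output — together with a synthetic-data module that generates every input
with known ground truth, so each stage can be scored by parameter recovery.

# Marker model

Markers are **parent-diagnostic 51-mer pairs**. Comparing the canonical
k-mer content of the two inbred parents, a k-mer `x` is A-diagnostic when it
is abundant in parent A and (effectively) absent in parent B while a
single-base substitution `y` of `x` shows the mirror pattern. Each SNV with
unique flanks yields up to k = 51 such pairs, one per covering window. The
marker at this stage is just the k-mer plus its line tag — no coordinates —
which is what makes the approach assembly-independent. Coordinates come
later by exact unique placement on the draft contigs: a pair is kept only
when exactly one of its two k-mers occurs exactly once (either orientation)
across the assembly. k must be odd so canonical form is unambiguous; 51 is
long enough that a random 51-mer essentially never recurs in a half-gigabase
genome, yet short enough to fit ~50 times in a 100-bp read.

Count thresholds are exposed (`min_count`, `max_other`): counting from
assembled genomes the natural thresholds are 1/0; counting from WGS reads,
3/0 suppresses sequencing-error k-mers.

## Marker panel design: the reduced-representation filter

GBS only observes the ends of size-selected restriction fragments, and which
fragment a haplotype produces is itself allele-dependent: an SNV that
creates or destroys a `GCWGC` site in one parent moves that haplotype's
fragment out of the size-selection window. Markers in such regions suffer
*allele-specific dropout* — one allele is simply never sequenced — and at
genotyping time a heterozygote masquerades as a clean homozygote at every
one of the ~50 loci covering the neighbouring SNV. Because the two parental
genomes are in hand at discovery time, this is predictable:
`filter_markers_gbs()` digests both parents in silico, emits the
deterministic fragment-end read set each would produce under the declared
size selection and read length, and keeps only pairs whose A k-mer is
visible in parent A's reads *and* whose B k-mer is visible in parent B's.
In our simulations this removes ~90% of raw pairs (most of the genome is
not within a read length of a retained cut site) and, more importantly, all
systematically biased loci.

# Genotyping and consensus binning

Demultiplexing assigns a read to the unique sample whose inline barcode,
followed by a base matching the `CWGC` ApeKI remnant, prefixes it; barcodes
are tried longest-first, trimmed, and the remnant retained. Genotyping then
slides a 51-bp window over every read and counts exact canonical matches to
the placed marker k-mers, giving per-individual, per-locus counts of the A
and B alleles. Calls are threshold-based: `AA` needs `count_a >= 2` with no
B observations (`min_allele`, config-exposed), `AB` needs at least one of
each. One stray read cannot produce a homozygote call, while hets remain
callable at modest depth.

Raw calls are noisy and massively redundant (up to 51 loci per SNV), so they
are consolidated by **majority-rule binning in 14-kb windows** tiling each
contig (anchored at 0, half-open, last window truncated). Two details of the
voting are deliberate:

* *One vote per marker site.* Loci whose k-mer windows overlap (starts
  within 51 bp, chained) cover the same SNV and are collapsed to a single
  plurality vote first. Without this, a single aberrant site — residual
  dropout, a repeat edge case — contributes dozens of correlated wrong
  calls and can outvote every clean site in the window.
* *Strict plurality with support.* The window consensus must beat every
  rival outright and the winning class must be backed by at least
  `min_calls = 2` raw calls; ties or thin support give `U` (unknown).

A window that contains a crossover for some individual genuinely has no
single genotype; those windows resolve to whichever side carries more
sites, and the evaluation module scores only crossover-free windows, where
a unique truth exists.

# Linkage map construction

The consensus matrix (windows x individuals over `{A,H,B,U}`) feeds a
standard F2 mapping pipeline built from three pieces.

**Pairwise recombination fractions.** For each pair of loci the 3x3 joint
genotype table is scored against the F2 two-locus class probabilities
(parental `(1-r)^2/4`, single-recombinant `r(1-r)/2`, double `r^2/4`, with
the double-heterozygote class pooling both phase configurations to
`((1-r)^2 + r^2)/2`). The likelihood is maximised on a dense grid (step
0.001) followed by golden-section refinement — deterministic, no EM
convergence ambiguity. LOD is `log10 L(r-hat)/L(0.5)`. A locus observed in
fewer than two genotype classes is declared uninformative (`r = 0.5`,
`LOD = 0`): a degenerate margin cannot distinguish linkage from distortion,
and without this guard two distorted windows on different chromosomes would
score `r = 0` with LOD growing linearly in n. Segregation distortion itself
is only *flagged* (`segregation_chisq()`), never silently filtered.

**Grouping.** Single linkage: connected components of the graph with an
edge wherever `r <= 0.35` and `LOD >= 6`. With ~100 individuals,
same-chromosome windows 14 kb apart (a few cM) link with LOD far above 6,
while LOD >= 6 between unlinked loci is essentially impossible, so the
defaults separate chromosomes cleanly. Loci with no qualifying edge become
singleton groups, reported but excluded from the map.

**Ordering.** Within a group: minimum spanning tree of the r-weighted
complete graph, its weighted diameter path as backbone, remaining loci
inserted at the adjacent-r-sum-minimising slot, then a windowed ripple (all
permutations of a sliding window of 5) accepted only on strict improvement
of the objective — the sum of adjacent recombination fractions, i.e. the
expected crossover count per meiosis along the order. The published MSTMap
idea is followed in spirit (MST + local improvement under a count
objective), not re-implemented bit-for-bit; correctness is judged by truth
recovery, not output identity. Cumulative positions are prefix sums of the
Kosambi map function `d = 25 ln((1+2r)/(1-2r))` cM over adjacent pairs; a
map is defined only up to reversal, and every downstream consumer respects
that freedom.

# Misjoin detection and scaffolding

A chimeric contig reveals itself when most of the population changes
genotype at the same window boundary: across a junction joining unlinked
regions the expected switch fraction is `1 - (1/4^2 + 1/2^2 + 1/4^2) =
0.625`, while across a genuine 14-kb step it is roughly the per-window
recombination fraction (well under 0.1). `detect_misjoins()` therefore
reports boundaries where at least half the informative individuals
(`min_switch = 0.5`) switch, with at least 20 individuals informative on
both sides; runs of adjacent qualifying boundaries merge to the strongest
one. Splits happen only at window boundaries — the detection resolution —
so `split_contigs()` is exact and reversible, and window relabelling after
a split (`apply_breakpoints()`) is a pure re-anchoring.

Scaffolding assigns each contig (part) to the group holding the majority of
its mapped windows (conflicts flagged as candidate undetected chimeras),
orients it by the sign of the Kendall correlation between window midpoints
and cM positions (`?` when fewer than two distinct positions exist; emitted
as `+` and flagged), orders parts by median cM with lexicographic
tie-breaks, and concatenates them with 100-N gaps into pseudomolecules.
The AGP v2.1 table alternates `W` and `U` rows (`gap_type` "map", linkage
"yes") and is bit-exactly invertible: rebuilding the FASTA from the AGP
plus contigs reproduces the emitted sequences. Unplaced parts are carried
as standalone scaffolds rather than forced into a chromosome.

# The synthetic study

The simulator generates the study the package is designed around: two fully
inbred parents differing only by substitutions (default rate 0.002/bp), an
F2 population as recombinant mosaics (Poisson crossovers, mean 1.5 per
chromosome per gamete — a 150-cM chromosome — uniform positions, no
interference, founder of the first segment a fair coin), ApeKI digestion
with size selection 60-400 bp, and barcoded single-end 100-bp reads at
Poisson depth per retained fragment end. Right-hand fragment ends are read
off the bottom strand and include the 3-bp overhang of their cut site, so
every read starts at the `CWGC` remnant, exactly as ApeKI library chemistry
dictates; fragment ends at chromosome termini carry no ligatable cut and
emit no read. Reads carry substitution errors only (matching the exact-match
genotyping model); barcodes are error-free. The draft assembly is the
parent-A genome cut at uniform positions (minimum contig length enforced),
each contig reverse-complemented with probability 1/2 and the naming
shuffled; chimeras join two pieces from different chromosomes so the layout
still covers the genome and each junction offset is recorded.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate — includes indel and structural variation between parents,
PCR duplicates, quality-score variation, barcode synthesis errors,
repeat-induced multi-mapping beyond what random sequence produces, and
segregation distortion of biological origin. Defaults not fixed by the
study design (mean depth 4, size selection 60-400) are exposed in
`sim_config()` and held fixed across all tests.

Every stage is scored against the recorded truth by
`evaluate_against_truth()`: genotype accuracy over crossover-free windows,
|Kendall tau| between map order and true bp order per group (absolute value:
reversal freedom), breakpoint recall/precision with a one-window tolerance,
and orientation accuracy up to per-group reversal.

# Numerical choices and degenerate inputs

* Canonical k-mers are 2-bit packed into 128-bit integers (k <= 63, odd);
  windows containing `N` are skipped.
* The rf grid spans [0, 0.5] inclusive so complete linkage (r = 0) and
  independence (r = 0.5, LOD 0) are exactly representable; golden-section
  refinement keeps whichever of the refined and grid optimum scores higher,
  so degenerate tables resolve to exact endpoints.
* Adjacent fractions >= 0.5 in an accepted order are clamped to 0.499 with
  a warning before the Kosambi transform.
* Ties everywhere break deterministically (lexicographic ids, first-index
  rules), and all randomness flows from a single config seed through
  per-stage derived streams, so identical configs give bit-identical
  outputs including FASTA/FASTQ files.
* Contigs with fewer than two windows cannot be oriented (`?`), terminal
  windows are truncated rather than padded, and empty inputs (no markers,
  no breakpoints, empty groups) return empty but well-typed tibbles.

# Problem sizes

The bundled tests and the acceptance script run the full design at desk
scale, chosen so the whole suite completes in minutes on one CPU: nine
500-kb chromosomes, 96 individuals and 60 contigs for the end-to-end study
(about 5.8 million simulated reads); two 250-kb chromosomes at depth 10 for
the exact-reconstruction check; and two 100-kb chromosomes for the
288-individual demultiplexing run. Genetic parameters (marker density per
window, cM between windows, switch fractions) are scale-free, so recovery
behaviour at desk scale mirrors the full-genome setting; absolute marker
counts and N50-style statistics of course do not.

# Known limitations

* Exact-match placement assumes the assembly derives from parent A; a
  consensus-polished or higher-error assembly would need the aligner-based
  placement the package deliberately omits.
* Ordering is pairwise-likelihood based; multipoint HMM genotype correction
  and imputation of `U` windows are out of scope.
* Misjoin detection resolves to one window (14 kb); sub-window junction
  refinement is not attempted.
* Joins across linkage-group boundaries, gap-size estimation from genetic
  distance, and Hi-C/optical-map integration are out of scope.

# A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_chromosomes = 2, chromosome_length = 250000,
                  n_individuals = 96, mean_depth = 10, error_rate = 0,
                  n_contigs = 10, seed = 7)
truth <- simulate_parents(cfg) |>
  simulate_f2_population() |>
  fragment_reference()
run <- simulate_gbs_run(truth)

markers <- discover_markers(count_kmers(unname(truth$haplotype_a), 51),
                            count_kmers(unname(truth$haplotype_b), 51),
                            k = 51, min_count = 1, max_other = 0) |>
  filter_markers_gbs(truth$haplotype_a, truth$haplotype_b, k = 51)
placed <- place_markers(markers, truth$contigs, k = 51)$placed

consensus <- demultiplex(run$reads, run$barcodes) |>
  count_alleles(placed, k = 51) |>
  call_genotypes() |>
  bin_consensus(setNames(nchar(truth$contigs), names(truth$contigs)))

map <- fit_genetic_map(consensus)
autoplot(map)
pm <- build_pseudomolecules(place_contigs(map, truth$contigs), truth$contigs)
evaluate_against_truth(truth, consensus = consensus, map = map,
                       placements = pm$placements)
```
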