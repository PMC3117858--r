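---
title: "Designing a SNP genotyping array from pooled reduced-representation sequencing"
author: "rrlchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a SNP genotyping array from pooled reduced-representation sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlchip)
```

## The problem

A medium-density genotyping array is only useful if its SNPs (i) convert
into working assays, (ii) segregate at usable minor allele frequencies
(MAF) in the populations of interest, and (iii) cover the genome evenly.
`rrlchip` implements the computational pipeline behind one proven recipe,
developed for the chicken 60K BeadChip: sequence *pooled* DNA of a few
populations over a *reduced representation* of the genome (a size-selected
restriction digest), call SNPs from deep pileups, estimate each SNP's MAF
by counting reads per allele, and then select array content by priority
classes and per-chromosome spacing. Markers on sequence missing from the
assembly are afterwards placed by two-point linkage in full-sib families.

All inputs can be produced by the package's synthetic-data layer with
known ground truth, so every stage is testable by recovery.

## Reduced representation arithmetic

`digestGenome()` cuts at every exact occurrence of the enzyme site
(default AluI, `AG^CT`, a blunt palindromic four-cutter, so matching the
forward strand suffices; non-palindromic sites are also matched as their
reverse complement with the cut mapped back). The fragments tile each
chromosome exactly — this is asserted as a class invariant.
`selectFraction()` keeps fragments inside an inclusive length window
(defaults 125–200 bp, stated inclusively because gel excision windows
are), and `expectedDepth()` is the identity `depth = sequenced bases /
selected bases` linking genome fraction, sequencing yield and coverage.

On an i.i.d. genome with uniform base composition the expected cut rate is
$(1/4)^4$ per position, about one fragment per 256 bp, so a 125–200 bp
window selects roughly 10% of a random genome. Real genomes deviate;
the window and enzyme are parameters, not constants.

## Pooled read simulation

`simulatePoolReads()` emulates 36 bp paired-end sequencing of an equimolar
pool of 25 diploids: each read pair covers the two ends of a size-selected
fragment, so after an internal `AG^CT` cut both mates begin with `CT` on
their own strand — exactly the property the start-motif read filter
exploits. The template haplotype of each pair is drawn i.i.d. from the
pool's 50 founder haplotypes; founder alleles at each planted SNP are
drawn once per pool from the planted population frequency. The alt base
is therefore emitted with probability equal to the *realized* pool
frequency, which differs from the planted one by haplotype-sampling noise
of variance $p(1-p)/50$ — this term matters when judging MAF accuracy
(below). Sequencing error substitutes a uniformly chosen different base;
qualities follow a two-state model (default Q35 bodies with 2% of reads
at Q8) so the mean-quality filter has positive cases. The model does not
attempt real Illumina error profiles, indels, structural variants or
sex-chromosome dosage; conclusions from passing tests are about the
pipeline's logic, not about platform-specific artefacts.

The planted MAF spectrum defaults to uniform on [0.1, 0.5] (mean 0.30),
the flat, high-MAF spectrum that pooled RRL discovery targets; a
`share` parameter (default 0.5) controls how often two populations reuse
the same frequency draw. SNPs fixed in individual lines are not modelled.

## Read QC

Four filters, in a fixed order with first-failure attribution so the
report's counts conserve (`input = retained + sum(removed)`):

* mean Phred quality strictly below 12 (strict `<`, so a uniform Q12 read
  survives);
* first two bases not `CT` (the residual AluI motif; `N` never matches);
* a homopolymer run longer than 17 bases (half the 36 bp read length;
  `N` breaks runs);
* after alignment, reads at start sites observed more than 5× the mean
  depth. A "site" is the (chromosome, start, strand) key — RRL reads
  stack at cut sites, making start multiplicity the natural unit. Mean
  depth is estimated as aligned bases over covered bases, overridable.

Filters are applied per read; dropping one mate never drops the other,
and the motif filter applies to both mates by default (both ends of a
blunt-cut fragment carry the motif).

## Mapping and SNP calling

`mapReads()` is a minimal unique-location mapper for fixed-length
synthetic reads: exact hits by hashing all reference k-mers of the read
length, 1-mismatch hits by two half-read exact seeds, both strands. A
read is `unique` only with a single best location; ties are `multi` and
never enter the pileup. Map qualities are 37 (unique, 0 mismatches) and
25 (unique, 1 mismatch) — only the ≥10 threshold downstream consumes
them. Externally produced SAM can be ingested instead
(`readSamAlignments()`), in which case the file's own MAPQ is used.

`callSnps()` applies the pooled calling rules: reads under map quality 10
are excluded; a site is called when exactly two alleles each have ≥3
reads (one of them the reference base), site depth is at most 4× the mean
(paralogue guard), the best read has map quality ≥10 and the consensus
quality is ≥10. Consensus quality is defined here as the Phred-scaled
log-likelihood ratio of "biallelic with the two observed alleles, allele
fraction at its ML value" versus "monoallelic reference", under
independent per-read errors given the base qualities, capped at 60. Sites
with more than two supported alleles, without reference support, or in
spacer runs of an augmented reference are counted in a rejects report,
never called. MAF is estimated by direct read counting:
`min(ref, alt) / (ref + alt)`.

`mergePopulations()` combines per-population calls by position; allele
pairs conflicting between populations are flagged and excluded from the
summary (a rare, deliberately conservative choice), the overall MAF is
count-weighted across populations, and the MAF histogram uses fixed 0.05
bins over [0, 0.5].

Contigs absent from the assembly are carried by
`buildAugmentedReference()`: contigs ≥200 bp are concatenated into one
artificial chromosome with 100 bp N spacers (longer than a read, so no
read spans two contigs); the offset table makes artificial coordinates
invertible, and spacer positions are never callable.

## Panel design

Eligibility is Infinium type II (A/C, A/G, T/C, T/G — single bead type),
design score ≥0.6 (scores come from a vendor tool; the synthetic stand-in
only reproduces threshold behaviour), and no other variant within 10 bp.
Eligible candidates fall into 25 priority classes: five
source/validation levels (validated; RRL+database; RRL novel with MAF in
both broiler and layer groups; RRL novel with MAF in one group; database
only, no MAF) crossed with five MAF tiers on the mean available group MAF
(≥0.3, 0.2–0.3, 0.1–0.2, 0.05–0.1, <0.05 or absent). The tier-1 boundary
of 0.3 makes "validated with high MAF in both groups" class 1 and
"database SNP, never assayed, no MAF" class 25, the two anchors of the
scheme. The table is an argument, not a constant.

Spacing follows chromosome size class: 20 kb on macro-chromosomes, 4 kb
on micro-chromosomes (their per-bp recombination rate is severalfold
higher), geometric-mean interpolation for the intermediate class. The
selector scrolls along each chromosome: from cursor `c` it examines the
window `(c + s/2, c + 3s/2]` (spacing `s`), picks the best candidate —
lowest class, ties to higher mean MAF, then leftmost — moves the cursor
there, and records a gap when the window is empty. The window rule and
tie-breaks are this package's explicit determinization of "highest
priority at regular distances"; the procedure is fully deterministic, and
a uniform rescaling of class numbers cannot change the selection. Add-on
sets (unplaced contigs, chr_random, mitochondrion) bypass spacing and
eligibility by design.

## Array performance classification

`simulateAssay()` is a genotype-level stand-in for the assay and its
cluster calling: per-SNP design failure (default 5%), per-SNP clustering
failure (default 2%), Hardy–Weinberg genotypes per breed. Intensity-space
clustering is out of scope. `classifyPerformance()` partitions SNPs into
`failed` (design), `excluded` (unclusterable, only heterozygotes, or no
calls at all), `monomorphic`, and `polymorphic` (both alleles seen within
at least one breed — two breeds fixed for different alleles do *not*
count). `validationTable()` reports percentages with the failed share
over the group total and the other three shares over SNPs passing design;
the published validation table for the 60K chip is consistent with this
denominator convention, which is why the package adopts it.

## Two-point linkage placement

Transmissions are read off full-sib families per parent; the fully
ambiguous AB×AB→AB configuration contributes nothing (a simplification
relative to full multipoint treatments). Parental phase is chosen by
maximizing the two-point likelihood, equivalently counting the minority
transmission class as recombinant, giving
$\hat\theta = \min(R/N, 0.5)$ and
$\mathrm{LOD} = \log_{10}\left[\hat\theta^{R}(1-\hat\theta)^{N-R}/0.5^{N}\right]$
(0 at $\hat\theta = 0.5$). A Mendelian-error screen precedes linkage.
Unmapped markers join a chromosome only when ≥2 mapped markers there
exceed the LOD threshold and no other chromosome qualifies; new linkage
groups are connected components of the LOD>4 graph among the remaining
markers, singletons excluded. Distances are reported with the Kosambi
function $d = 25\ln[(1+2\theta)/(1-2\theta)]$; crossover *simulation*
uses no interference (Haldane), since $\theta$ is what the estimator
sees and Kosambi is only the reporting convention. Ordering within a
group is greedy two-point (ends anchored at the most distant confident
pair, interior markers ordered by distance to one anchor), deliberately
coarser than multipoint ordering, so map lengths are not comparable to
multipoint maps.

### What the recovery experiment shows — and does not

The standard recovery scenario plants two hidden micro-chromosomes with
15 and 13 markers at 1.5 cM spacing (every within-group recombination
fraction ≤0.2) in two families totalling 92 offspring, and asks for
exactly two recovered groups, each pure for one true chromosome. Markers
without enough informative meioses stay unplaced — as in the real
experiment, where most contig-derived SNPs could not be placed either.
Two effects bound the success rate: with 92 offspring an end marker
occasionally tops out just below LOD 4 because its neighbours are
heterozygous in different parents (it stays unplaced, which the purity
criterion tolerates), and the phase-maximized LOD has a null tail of
roughly $6\times10^{-4}$ above 4, so among the ~195 between-group pairs a
spurious bridge merges the groups in a few percent of replicates. The
observed per-replicate success rate is about 0.96–0.97.

## Numerical and design choices

* Coordinates are 1-based, closed, throughout the package (the
  Bioconductor convention of `GRanges`/`IRanges`); BED export converts to
  0-based half-open, SAM and VCF are 1-based by definition.
* All generators take a `seed` and are bit-reproducible for a fixed seed.
* Problem sizes used by the tests and the acceptance script: a 240 kb
  four-class genome, planted SNP density 1/500 (a realistic between-line
  density for commercial chicken), four pools of 25 diploids at 30×
  over the selected fraction, and 100 replicates of the linkage
  scenario. These sizes make every property measurable while keeping the
  full suite fast.
* MAF accuracy is judged against the planted frequency with a 99%
  prediction interval from the two-stage sampling model
  ($\sqrt{p(1-p)(1/50 + 1/n)}$ with a continuity term), because the
  pool's 50 founder haplotypes contribute variance on top of read
  sampling.
* Ties in panel selection, group labelling (`LG1…` by size, then
  smallest member) and ordering are broken deterministically so repeated
  runs are byte-identical.

## Known limitations

Pool simulation has no inter-individual DNA-quantity imbalance; the
mapper handles at most one mismatch and no indels; conflicting allele
pairs between populations are dropped rather than reconciled; the
depth cap uses the per-population mean; intensity-level cluster quality
is reduced to a Bernoulli flag; and linkage ordering is two-point greedy.
Each of these is a deliberate scope boundary, noted where it affects an
interface.
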