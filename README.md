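# rrlchip

Design a medium-density SNP genotyping array from pooled
reduced-representation sequencing — the strategy behind the chicken 60K
BeadChip — as a tested, reusable R pipeline.

The package is for people building (or studying how to build) genotyping
arrays for species where a few deeply sequenced DNA pools must yield both
the SNPs and their minor allele frequencies (MAF). It covers, end to end:

* **Reduced representation library (RRL) design** — in-silico restriction
  digestion (`digestGenome()`, default AluI `AG^CT`), inclusive fragment
  size selection (`selectFraction()`), and the coverage/depth identity
  `depth = sequenced bp / selected bp` (`expectedDepth()`).
* **Read QC** — the four RRL filters with first-failure accounting: mean
  Phred < 12, first two bases ≠ `CT`, homopolymer runs > 17 of 36 bases,
  and alignment start sites over 5× the mean depth (`runReadQc()`,
  `filterOverrepresentedSites()`).
* **Pooled SNP discovery** — a unique-location mapper for synthetic
  36-mers (`mapReads()`; SAM ingestion via Rsamtools as an alternative),
  pileup calling under the pooled thresholds (both alleles ≥ 3 reads,
  depth ≤ 4× mean, map/consensus qualities ≥ 10; `callSnps()`), MAF by
  direct read counting `min(ref, alt)/(ref + alt)` (`estimateMaf()`),
  population merging and an augmented reference that carries unplaced
  contigs ≥ 200 bp as one artificial spacered chromosome.
* **Panel design** — Infinium type II screening (A/C, A/G, T/C, T/G),
  design score ≥ 0.6, a 10 bp neighbour-SNP exclusion, a configurable
  25-class priority lattice, chromosome-size-dependent spacing (20 kb
  macro → 4 kb micro), and the deterministic scroll-and-select walk
  (`selectPanel()`, `assembleManifest()`).
* **Array validation** — the four performance classes (failed / excluded /
  monomorphic / polymorphic) and validation tables whose non-failed
  percentages use the passing-design denominator (`validationTable()`).
* **Linkage placement** — Mendelian screening, phase-maximized two-point
  LOD (`twopoint()`), chromosome assignment requiring multiple
  supporters, new linkage groups as LOD > 4 graph components
  (`buildNewGroups()`), Kosambi distances
  `d = 25·ln[(1+2θ)/(1−2θ)]` (`kosambiCm()`).
* **Synthetic data with ground truth** — genomes with avian-style
  macro/micro size classes and GC bias, planted SNPs with a flat
  high-MAF spectrum, pooled 36 bp paired-end reads starting at cut
  sites, design scores, and full-sib mapping families
  (`generateGenome()`, `plantSnps()`, `simulatePoolReads()`,
  `simulateFamilyGenotypes()`).

See `vignettes/rrlchip-methods.Rmd` for the models, assumptions and
design choices.

## Worked example

Discovery on a synthetic 240 kb genome, one pool of 25 birds at 30×:

```r
library(rrlchip)

g    <- generateGenome(seed = 1)              # 240 kb, 4 size classes
snps <- plantSnps(g, seed = 2)                # truth SNPs, flat MAF spectrum
inv  <- digestGenome(g)                       # AluI fragments
sel  <- selectFraction(inv, sizeWindow(125, 200))
pr   <- simulatePoolReads(g, snps, inv, sizeWindow(125, 200),
                          poolSpec("B1", 25, 30), seed = 3)
qc   <- runReadQc(c(pr$mate1, pr$mate2))
aln  <- uniqueAlignments(mapReads(qc$reads, g))
out  <- callSnps(aln, g, populationId = "B1")
```

This prints / returns:

```
SyntheticGenome: 4 chromosome(s), 240,000 bp
  classes: intermediate=1, macro=1, micro=2
planted SNPs: 479
selected 25135 bp (10.5% of the genome) in 156 fragments
QcReport: 20946 reads in, 20352 retained
  removed by mean_quality: 445
  removed by start_motif: 149
  removed by homopolymer: 0
called 15 SNPs, mean MAF 0.292, mean depth 65.6
 chrom  pos ref alt ref_count alt_count       maf
  chr1 1820   G   A        34        26 0.4333333
  chr1 1948   C   A        45        13 0.2241379
  chr1 3783   G   T        22        20 0.4761905
```

Reading it: ~10% of the genome falls in the 125–200 bp AluI window, so
30× over the selection costs only ~0.75 Mb of sequence. The QC report
conserves counts (input = retained + removed; the low-quality and
wrong-start reads are simulated on purpose). Only fragment ends are
covered by 36 bp reads, so of the 479 planted SNPs the ~20 inside covered
bases are recoverable — every call sits on a planted SNP, with its MAF
estimated from the allele read counts. Merging the four pools, scoring
candidates, selecting the panel and classifying array performance
continue from here (`mergePopulations()`, `buildCandidateTable()`,
`selectPanel()`, `simulateAssay()`, `validationTable()`).

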