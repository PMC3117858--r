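#' Build a base-level pileup from unique alignments
#'
#' Expands fixed-length alignments into per-position base counts broken down
#' by base quality, plus per-site depth and best map quality. Only the
#' alignments passed in contribute — pass [uniqueAlignments()] output so
#' multi-mapping reads are excluded. `N` bases are dropped.
#'
#' @param alignments `data.frame` with `chrom`, `pos`, `mapq`, `seq`,
#'   `qual` (reference-oriented, fixed width).
#' @param minMapq Reads with map quality below this are excluded from the
#'   pileup (default 0: keep all; the caller applies its own threshold).
#' @return `list(bases, sites)`: `bases` is a data.table with columns
#'   `chrom`, `pos`, `base`, `qual`, `n`; `sites` has `chrom`, `pos`,
#'   `depth`, `best_mapq`.
#' @export
buildPileup <- function(alignments, minMapq = 0) {
  aln <- alignments[!is.na(alignments$pos) & alignments$mapq >= minMapq, ,
                    drop = FALSE]
  if (nrow(aln) == 0)
    return(list(bases = data.table(chrom = character(), pos = integer(),
                                   base = character(), qual = integer(),
                                   n = integer()),
                sites = data.table(chrom = character(), pos = integer(),
                                   depth = integer(),
                                   best_mapq = integer())))
  L <- nchar(aln$seq[1])
  nR <- nrow(aln)
  dt <- data.table(
    chrom = rep(aln$chrom, each = L),
    pos = rep(aln$pos, each = L) + rep.int(0:(L - 1L), nR),
    base = unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE),
    qual = utf8ToInt(paste(aln$qual, collapse = "")) - 33L,
    mapq = rep(aln$mapq, each = L))
  dt <- dt[base != "N"]
  bases <- dt[, .(n = .N), by = .(chrom, pos, base, qual)]
  sites <- dt[, .(depth = .N, best_mapq = max(mapq)), by = .(chrom, pos)]
  setkey(bases, chrom, pos)
  setkey(sites, chrom, pos)
  list(bases = bases, sites = sites)
}

# Phred-scaled support for the site being biallelic (ref+alt as observed)
# versus monoallelic reference, under independent per-read errors with the
# allele fraction plugged in at its ML value; capped at `cap`.
.consensusQuality <- function(refBase, altBase, baseDT, cap = 60) {
  e <- 10^(-baseDT$qual / 10)
  pRef <- ifelse(baseDT$base == refBase, 1 - e, e / 3)
  pAlt <- ifelse(baseDT$base == altBase, 1 - e, e / 3)
  nRef <- sum(baseDT$n[baseDT$base == refBase])
  nAlt <- sum(baseDT$n[baseDT$base == altBase])
  f <- nRef / (nRef + nAlt)
  llMono <- sum(baseDT$n * log(pRef))
  llBi <- sum(baseDT$n * log(f * pRef + (1 - f) * pAlt))
  min(cap, max(0, 10 / log(10) * (llBi - llMono)))
}

#' Call SNPs from pooled pileups
#'
#' Applies the pooled RRL calling rules: reads below the map-quality
#' threshold are excluded from counts; a site is called when exactly two
#' alleles are each supported by at least `minMinorReads` reads (one of
#' them the reference base), the site depth does not exceed
#' `maxDepthFactor` times the mean depth (paralogue guard), the consensus
#' quality is at least `minConsensus` and the best mapping read has map
#' quality at least `minBestMapq`. The minor allele frequency is estimated
#' by directly counting reads per allele. Sites falling in spacer runs of
#' an augmented reference are never called.
#'
#' @param alignments Unique alignments (see [uniqueAlignments()]).
#' @param reference The reference the reads were mapped to
#'   ([SyntheticGenome-class], [AugmentedReference-class] or named
#'   `DNAStringSet`); supplies the reference base per site.
#' @param populationId Population label stored with each call.
#' @param meanDepth Mean aligned depth; `NULL` estimates it from the
#'   alignments ([estimateMeanDepth()]).
#' @param minMapq,minConsensus,minBestMapq,minMinorReads,maxDepthFactor
#'   Calling thresholds (defaults 10, 10, 10, 3, 4).
#' @return `list(calls, rejects, meanDepth)`. `calls` is a `data.frame`
#'   with columns `population`, `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `maf`, `consensus_quality`, `best_mapq`; `rejects` a named
#'   count of sites rejected after the two-allele screen (`triallelic`,
#'   `ref_absent`, `depth_cap`, `consensus`, `best_mapq`).
#' @export
callSnps <- function(alignments, reference, populationId = "pool",
                     meanDepth = NULL, minMapq = 10, minConsensus = 10,
                     minBestMapq = 10, minMinorReads = 3,
                     maxDepthFactor = 4) {
  aln <- alignments[alignments$mapq >= minMapq, , drop = FALSE]
  if (is.null(meanDepth)) meanDepth <- estimateMeanDepth(aln)
  if (meanDepth <= 0) stop("meanDepth must be > 0")
  pu <- buildPileup(aln)
  seqs <- if (is(reference, "DNAStringSet")) reference else
    genomeSequences(reference)
  chromStr <- as.character(seqs)

  rejects <- c(triallelic = 0L, ref_absent = 0L, depth_cap = 0L,
               consensus = 0L, best_mapq = 0L)
  empty <- data.frame(population = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      ref_count = integer(), alt_count = integer(),
                      maf = numeric(), consensus_quality = numeric(),
                      best_mapq = integer(), stringsAsFactors = FALSE)
  if (nrow(pu$bases) == 0)
    return(list(calls = empty, rejects = rejects, meanDepth = meanDepth))

  alleleCounts <- pu$bases[, .(count = sum(n)), by = .(chrom, pos, base)]
  alleleCounts[, npass := sum(count >= minMinorReads), by = .(chrom, pos)]
  cand <- unique(alleleCounts[npass >= 2L, .(chrom, pos, npass)])

  # mask spacer positions of an augmented reference
  if (is(reference, "AugmentedReference") && nrow(cand) > 0) {
    sp <- .spacerRanges(reference)
    if (length(sp) > 0) {
      gr <- GenomicRanges::GRanges(cand$chrom,
                                   IRanges::IRanges(cand$pos, width = 1))
      hit <- GenomicRanges::countOverlaps(gr, sp) > 0
      cand <- cand[!hit]
    }
  }

  calls <- list()
  for (k in seq_len(nrow(cand))) {
    ch <- cand$chrom[k]; p <- cand$pos[k]
    ac <- alleleCounts[chrom == ch & pos == p]
    passing <- ac[count >= minMinorReads]
    if (nrow(passing) > 2L) {
      rejects["triallelic"] <- rejects["triallelic"] + 1L
      next
    }
    refBase <- substring(chromStr[[ch]], p, p)
    if (!refBase %in% passing$base) {
      rejects["ref_absent"] <- rejects["ref_absent"] + 1L
      next
    }
    altBase <- passing$base[passing$base != refBase]
    site <- pu$sites[chrom == ch & pos == p]
    if (site$depth > maxDepthFactor * meanDepth) {
      rejects["depth_cap"] <- rejects["depth_cap"] + 1L
      next
    }
    if (site$best_mapq < minBestMapq) {
      rejects["best_mapq"] <- rejects["best_mapq"] + 1L
      next
    }
    bq <- pu$bases[chrom == ch & pos == p]
    cq <- .consensusQuality(refBase, altBase, bq)
    if (cq < minConsensus) {
      rejects["consensus"] <- rejects["consensus"] + 1L
      next
    }
    nRef <- passing$count[passing$base == refBase]
    nAlt <- passing$count[passing$base == altBase]
    calls[[length(calls) + 1L]] <- data.frame(
      population = populationId, chrom = ch, pos = p, ref = refBase,
      alt = altBase, ref_count = nRef, alt_count = nAlt,
      maf = estimateMaf(nRef, nAlt), consensus_quality = cq,
      best_mapq = site$best_mapq, stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else empty
  rownames(calls) <- NULL
  list(calls = calls, rejects = rejects, meanDepth = meanDepth)
}

#' Minor allele frequency from read counts
#'
#' `maf = min(refCount, altCount) / (refCount + altCount)` — the estimator
#' used for pooled libraries, where each read is one sampled haplotype.
#'
#' @param refCount,altCount Non-negative read counts; their sum must be
#'   positive.
#' @return MAF in \[0, 0.5\].
#' @export
estimateMaf <- function(refCount, altCount) {
  tot <- refCount + altCount
  if (any(tot <= 0)) stop("zero total read count")
  pmin(refCount, altCount) / tot
}

#' Combine per-population SNP calls
#'
#' Merges calls keyed by (chrom, pos). Sites whose allele pair differs
#' between populations are flagged `conflict` and excluded from the
#' summary. The overall MAF is count-weighted: read counts are pooled
#' across populations before folding to the minor allele. Sites present in
#' `knownTable` are flagged as known.
#'
#' @param callsList Named list of `calls` data.frames from [callSnps()]
#'   (one per population).
#' @param knownTable Optional `data.frame` with columns `chrom`, `pos` of
#'   previously known SNPs.
#' @param histogramBreaks MAF histogram bin edges (default 0.05 bins over
#'   \[0, 0.5\]).
#' @return `list(merged, summary)`: `merged` has one row per site with
#'   `chrom`, `pos`, `ref`, `alt`, `n_populations_detected`, `known_flag`,
#'   `conflict`, `overall_maf` and per-population `maf_<pop>` columns;
#'   `summary` lists `n_total`, `n_in_ge2_pops`, `n_known`, `mean_maf` and
#'   `maf_histogram` (computed over non-conflicting sites).
#' @export
mergePopulations <- function(callsList, knownTable = NULL,
                             histogramBreaks = seq(0, 0.5, by = 0.05)) {
  stopifnot(length(callsList) > 0, !is.null(names(callsList)))
  all <- rbindlist(lapply(names(callsList), function(p) {
    x <- as.data.table(callsList[[p]])
    x[, population := p]
    x
  }), use.names = TRUE)
  if (nrow(all) == 0)
    return(list(merged = data.frame(), summary = list(
      n_total = 0L, n_in_ge2_pops = 0L, n_known = 0L, mean_maf = NA_real_,
      maf_histogram = NULL)))
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  all[, pair := pairKey(ref, alt)]
  merged <- all[, .(
    ref = ref[1], alt = alt[1],
    n_populations_detected = uniqueN(population),
    conflict = uniqueN(pair) > 1L,
    overall_maf = {
      tr <- sum(ref_count); ta <- sum(alt_count)
      min(tr, ta) / (tr + ta)
    }), by = .(chrom, pos)]
  for (p in names(callsList)) {
    x <- as.data.table(callsList[[p]])[, .(chrom, pos, maf)]
    setnames(x, "maf", paste0("maf_", p))
    merged <- merge(merged, x, by = c("chrom", "pos"), all.x = TRUE)
  }
  merged[, known_flag := FALSE]
  if (!is.null(knownTable) && nrow(knownTable) > 0) {
    kt <- as.data.table(knownTable[, c("chrom", "pos")])
    kt[, known_flag := TRUE]
    merged[kt, known_flag := TRUE, on = c("chrom", "pos")]
  }
  ok <- merged[conflict == FALSE]
  summary <- list(
    n_total = nrow(ok),
    n_in_ge2_pops = sum(ok$n_populations_detected >= 2L),
    n_known = sum(ok$known_flag),
    mean_maf = mean(ok$overall_maf),
    maf_histogram = table(cut(ok$overall_maf, breaks = histogramBreaks,
                              include.lowest = TRUE, right = FALSE)))
  list(merged = as.data.frame(merged), summary = summary)
}

#' Write SNP calls as VCF
#'
#' Minimal VCF 4.2 emission. Per-population calls carry `RO`, `AO`, `MAF`
#' in INFO and the consensus quality in QUAL; merged tables additionally
#' carry `NPOP` and `KNOWN`. 1-based positions as VCF requires.
#'
#' @param calls `calls` data.frame from [callSnps()].
#' @param file VCF path.
#' @return The file path, invisibly.
#' @export
writeSnpVcf <- function(calls, file) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rrlchip",
           "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele read count\">",
           "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele read count\">",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency from read counts\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tRO=%d;AO=%d;MAF=%.6g",
                 calls$chrom, calls$pos, calls$ref, calls$alt,
                 calls$consensus_quality, calls$ref_count, calls$alt_count,
                 calls$maf)
  writeLines(c(hdr, rec), file)
  invisible(file)
}

#' @rdname writeSnpVcf
#' @param merged `merged` data.frame from [mergePopulations()].
#' @export
writeMergedVcf <- function(merged, file) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rrlchip",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Count-weighted overall minor allele frequency\">",
           "##INFO=<ID=NPOP,Number=1,Type=Integer,Description=\"Populations the SNP was detected in\">",
           "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Previously known SNP\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("MAF=%.6g;NPOP=%d%s", merged$overall_maf,
                  merged$n_populations_detected,
                  ifelse(merged$known_flag, ";KNOWN", ""))
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                 merged$chrom, merged$pos, merged$ref, merged$alt,
                 ifelse(merged$conflict, "conflict", "PASS"), info)
  writeLines(c(hdr, rec), file)
  invisible(file)
}
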