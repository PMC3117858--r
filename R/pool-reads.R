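#' Pool specification
#'
#' One pooled sequencing library: equimolar DNA from `nIndividuals` diploids
#' of a single population, sequenced to `targetDepth` fold-coverage of the
#' size-selected fraction.
#'
#' @param populationId Population id; must match a `freq_<id>` column of the
#'   truth-SNP table.
#' @param nIndividuals Diploid individuals in the pool (default 25).
#' @param targetDepth Fold-coverage target over selected bases (default 30).
#' @return A list with class `PoolSpec`.
#' @export
poolSpec <- function(populationId, nIndividuals = 25, targetDepth = 30) {
  stopifnot(nIndividuals > 0, targetDepth >= 0)
  structure(list(populationId = populationId,
                 nIndividuals = as.integer(nIndividuals),
                 targetDepth = targetDepth),
            class = "PoolSpec")
}

#' Simulate paired-end reads from a pooled reduced-representation library
#'
#' Emulates Illumina sequencing of a size-selected restriction digest of
#' pooled DNA. Templates are fragments inside the size window; each read
#' pair covers the two fragment ends with `readLen` bases (36 bp paired-end
#' reads off AluI fragments, so after an internal AG^CT cut both mates start
#' with "CT" on their own strand). The template haplotype of each pair is
#' drawn i.i.d. from the pool's `2 * nIndividuals` founder haplotypes, whose
#' alleles at every truth SNP are drawn once per pool from the planted
#' population frequency; at a truth SNP the alternative base is therefore
#' emitted with probability equal to the realized pool allele frequency,
#' before sequencing error. Sequencing error substitutes a uniformly chosen
#' different base per position with probability `errorRate`. Qualities follow
#' a two-state model: most reads uniform high quality, an occasional read
#' uniformly low (so the mean-quality filter has positive cases).
#'
#' @param genome A [SyntheticGenome-class].
#' @param truthSnps GRanges from [plantSnps()].
#' @param fragmentSet A [FragmentInventory-class] from digesting `genome`,
#'   or a `GRanges` of fragments.
#' @param window A [sizeWindow()].
#' @param pool A [poolSpec()].
#' @param readLen Read length (default 36).
#' @param errorRate Per-base substitution error probability.
#' @param qualityModel `list(qHigh, qLow, pLowRead)`.
#' @param seed Optional integer seed.
#' @return A list of class `PoolReads` with elements `mate1`, `mate2`
#'   ([Biostrings::QualityScaledDNAStringSet]), `origins` (`data.frame` of
#'   true template coordinates per pair: `qname`, `chrom`, `fragStart`,
#'   `fragEnd`, `pos1`, `pos2`; mate1 maps forward at `pos1`, mate2 reverse
#'   at `pos2`), and `realizedFreq` (named alt-allele frequency realized in
#'   the pool's haplotypes at every truth SNP inside a selected fragment).
#' @export
simulatePoolReads <- function(genome, truthSnps, fragmentSet,
                              window = sizeWindow(), pool,
                              readLen = 36, errorRate = 0,
                              qualityModel = list(qHigh = 35, qLow = 8,
                                                  pLowRead = 0.02),
                              seed = NULL) {
  stopifnot(is(genome, "SyntheticGenome"), inherits(pool, "PoolSpec"))
  if (!is.null(seed)) set.seed(seed)
  frags <- if (is(fragmentSet, "FragmentInventory"))
    fragments(fragmentSet) else fragmentSet
  w <- IRanges::width(frags)
  sel <- frags[w >= max(window$minBp, readLen) & w <= window$maxBp]
  if (length(sel) == 0) stop("no template: size window selects no fragments")
  seqs <- genomeSequences(genome)
  chromStr <- as.character(seqs)

  selectedBp <- sum(IRanges::width(sel))
  nPairs <- max(1L, round(pool$targetDepth * selectedBp / (2 * readLen)))

  # realized pool haplotypes at truth SNPs inside selected fragments
  nHap <- 2L * pool$nIndividuals
  fcol <- paste0("freq_", pool$populationId)
  if (!fcol %in% names(S4Vectors::mcols(truthSnps)))
    stop("truth SNPs carry no frequencies for population ",
         pool$populationId)
  ov <- GenomicRanges::findOverlaps(truthSnps, sel)
  snpIdxSel <- sort(unique(S4Vectors::queryHits(ov)))
  nS <- length(snpIdxSel)
  H <- if (nS > 0) {
    f <- S4Vectors::mcols(truthSnps)[[fcol]][snpIdxSel]
    matrix(runif(nS * nHap) < rep(f, nHap), nrow = nS)
  } else matrix(logical(0), nrow = 0, ncol = nHap)
  realizedFreq <- if (nS > 0)
    stats::setNames(rowMeans(H), names(truthSnps)[snpIdxSel]) else
    stats::setNames(numeric(0), character(0))

  fi <- sample.int(length(sel), nPairs, replace = TRUE)
  hap <- sample.int(nHap, nPairs, replace = TRUE)
  chr <- as.character(GenomicRanges::seqnames(sel))[fi]
  s <- GenomicRanges::start(sel)[fi]
  e <- GenomicRanges::end(sel)[fi]
  m1 <- .charMatrix(substring(chromStr[chr], s, s + readLen - 1L), readLen)
  m2t <- .charMatrix(substring(chromStr[chr], e - readLen + 1L, e), readLen)

  # substitute pool-haplotype alt alleles at truth SNPs overlapping a mate
  if (nS > 0) {
    snpDT <- data.table(
      chrom = as.character(GenomicRanges::seqnames(truthSnps))[snpIdxSel],
      pos = GenomicRanges::start(truthSnps)[snpIdxSel],
      alt = truthSnps$alt[snpIdxSel],
      hrow = seq_len(nS))
    for (mateK in 1:2) {
      wstart <- if (mateK == 1) s else e - readLen + 1L
      readDT <- data.table(readIdx = seq_len(nPairs), chrom = chr,
                           ws = wstart, we = wstart + readLen - 1L)
      hitDT <- snpDT[readDT, on = .(chrom, pos >= ws, pos <= we),
                     .(readIdx = i.readIdx, hrow = x.hrow,
                       pos = x.pos, alt = x.alt),
                     nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hitDT) > 0) {
        isAlt <- H[cbind(hitDT$hrow, hap[hitDT$readIdx])]
        hitDT <- hitDT[isAlt]
        if (nrow(hitDT) > 0) {
          rel <- hitDT$pos - wstart[hitDT$readIdx] + 1L
          if (mateK == 1) m1[cbind(hitDT$readIdx, rel)] <- hitDT$alt
          else m2t[cbind(hitDT$readIdx, rel)] <- hitDT$alt
        }
      }
    }
  }

  # sequencing errors
  if (errorRate > 0) {
    for (m in c("m1", "m2t")) {
      mm <- get(m)
      hit <- which(matrix(runif(length(mm)) < errorRate, nrow = nrow(mm)),
                   arr.ind = TRUE)
      if (nrow(hit) > 0) {
        mm[hit] <- .otherBase(mm[hit])
        assign(m, mm)
      }
    }
  }

  mate1 <- .collapseRows(m1)
  # mate2 is the reverse complement of the fragment's 3' end
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  mate2 <- .collapseRows(matrix(comp[m2t[, readLen:1]], nrow = nPairs))

  qname <- sprintf("%s_read%07d", pool$populationId, seq_len(nPairs))
  qual1 <- ifelse(runif(nPairs) < qualityModel$pLowRead,
                  qualityModel$qLow, qualityModel$qHigh)
  qual2 <- ifelse(runif(nPairs) < qualityModel$pLowRead,
                  qualityModel$qLow, qualityModel$qHigh)
  mk <- function(strs, q, suffix) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(strs),
      Biostrings::PhredQuality(.phredString(q, readLen)))
    names(x) <- paste0(qname, suffix)
    x
  }
  structure(list(
    mate1 = mk(mate1, qual1, "/1"),
    mate2 = mk(mate2, qual2, "/2"),
    origins = data.frame(qname = qname, chrom = chr, fragStart = s,
                         fragEnd = e, pos1 = s, pos2 = e - readLen + 1L,
                         stringsAsFactors = FALSE),
    realizedFreq = realizedFreq,
    populationId = pool$populationId),
    class = "PoolReads")
}

#' Write paired reads as FASTQ
#'
#' Emits `<prefix>_1.fastq` / `<prefix>_2.fastq` with the `/1` `/2` read
#' name convention.
#'
#' @param poolReads A `PoolReads` list from [simulatePoolReads()].
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
writePoolFastq <- function(poolReads, prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  strip <- function(x) { S4Vectors::mcols(x) <- NULL; x }
  Biostrings::writeQualityScaledXStringSet(strip(poolReads$mate1), f1)
  Biostrings::writeQualityScaledXStringSet(strip(poolReads$mate2), f2)
  invisible(c(f1, f2))
}

#' Read a FASTQ file with qualities
#'
#' @param file FASTQ path.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(file) {
  # Biostrings notes that FASTQ carries no metadata columns; not of
  # interest here
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(file),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
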