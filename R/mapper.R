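#' Map short reads to unique reference locations
#'
#' A minimal seed-and-verify mapper for fixed-length synthetic reads
#' (default 36-mers). A read is reported `unique` when it has a single best
#' location (no tie at the best mismatch count) within `maxMismatch`
#' mismatches over both strands, `multi` when the best location is tied,
#' and `unmapped` otherwise. Only unique alignments receive a positive map
#' quality: 37 for a 0-mismatch unique hit, 25 for a 1-mismatch unique hit
#' (only the downstream >= 10 threshold matters). Exact hits are found by
#' hashing all reference k-mers of the read length; 1-mismatch hits via two
#' half-read exact seeds.
#'
#' @param reads A `QualityScaledDNAStringSet` (or `DNAStringSet`; qualities
#'   then default to Q35).
#' @param reference A [SyntheticGenome-class], [AugmentedReference-class]
#'   or named `DNAStringSet`.
#' @param maxMismatch 0 or 1 (default 1).
#' @param seedHitCap Seeds occurring more often than this in the reference
#'   are skipped (repeat guard).
#' @return `data.frame` with one row per read: `qname`, `status`
#'   (`unique`/`multi`/`unmapped`), `chrom`, `pos` (1-based leftmost),
#'   `strand`, `mapq`, `mismatches`, `seq`, `qual` (both reference-oriented;
#'   reads on `-` are reverse-complemented).
#' @export
mapReads <- function(reads, reference, maxMismatch = 1, seedHitCap = 100) {
  seqs <- if (is(reference, "SyntheticGenome") ||
              is(reference, "AugmentedReference"))
    genomeSequences(reference) else reference
  stopifnot(is(seqs, "DNAStringSet"))
  rs <- as.character(reads)
  qn <- names(reads)
  if (is.null(qn)) qn <- sprintf("read%07d", seq_along(rs))
  quals <- if (is(reads, "QualityScaledDNAStringSet"))
    as.character(Biostrings::quality(reads)) else
    .phredString(35L, nchar(rs))
  L <- unique(nchar(rs))
  if (length(L) != 1L) stop("mapReads requires fixed-length reads")

  chromStr <- as.character(seqs)
  chromLen <- nchar(chromStr)
  usable <- chromLen >= L
  out <- data.frame(qname = qn, status = "unmapped",
                    chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_, mapq = NA_integer_,
                    mismatches = NA_integer_, seq = rs, qual = quals,
                    stringsAsFactors = FALSE)
  if (!any(usable)) return(out)

  kmerTable <- function(k) {
    tabs <- lapply(which(usable), function(i) {
      n <- chromLen[i] - k + 1L
      data.table(kmer = substring(chromStr[i], 1:n, k:(chromLen[i])),
                 chrom = names(chromStr)[i], pos = 1:n)
    })
    dt <- rbindlist(tabs)
    setkey(dt, kmer)
    dt
  }
  t36 <- kmerTable(L)
  rc <- .revcompChar(rs)

  hitsOf <- function(x) t36[list(x), on = "kmer", nomatch = NULL]
  # exact stage: count hits of read and reverse complement
  dtF <- t36[data.table(kmer = rs, idx = seq_along(rs)), on = "kmer",
             nomatch = NULL, allow.cartesian = TRUE]
  dtR <- t36[data.table(kmer = rc, idx = seq_along(rs)), on = "kmer",
             nomatch = NULL, allow.cartesian = TRUE]
  dtF[, strand := "+"]; dtR[, strand := "-"]
  ex <- rbindlist(list(dtF, dtR))
  nhits <- integer(length(rs))
  if (nrow(ex) > 0) {
    # a palindromic read matches the same site on both strands; count once
    ex <- unique(ex, by = c("idx", "chrom", "pos"))
    cnt <- ex[, .N, by = idx]
    nhits[cnt$idx] <- cnt$N
    uni <- ex[idx %in% cnt$idx[cnt$N == 1L]]
    out$status[uni$idx] <- "unique"
    out$chrom[uni$idx] <- uni$chrom
    out$pos[uni$idx] <- uni$pos
    out$strand[uni$idx] <- uni$strand
    out$mapq[uni$idx] <- 37L
    out$mismatches[uni$idx] <- 0L
    out$status[nhits > 1L] <- "multi"
  }

  if (maxMismatch >= 1L) {
    todo <- which(nhits == 0L)
    if (length(todo) > 0) {
      half <- L %/% 2L
      t18 <- kmerTable(half)
      seedCount <- t18[, .N, by = kmer]
      mmCount <- function(a, b) {
        sum(charToRaw(a) != charToRaw(b))
      }
      for (i in todo) {
        cands <- list()
        for (strandK in c("+", "-")) {
          r <- if (strandK == "+") rs[i] else rc[i]
          for (seedOff in c(0L, L - half)) {
            seed <- substr(r, seedOff + 1L, seedOff + half)
            sc <- seedCount[list(seed), on = "kmer", nomatch = NULL]
            if (nrow(sc) == 0 || sc$N > seedHitCap) next
            h <- t18[list(seed), on = "kmer", nomatch = NULL]
            st <- h$pos - seedOff
            ok <- st >= 1L & st + L - 1L <= chromLen[h$chrom]
            if (!any(ok)) next
            cands[[length(cands) + 1L]] <-
              data.table(chrom = h$chrom[ok], pos = st[ok], strand = strandK,
                         read = r)
          }
        }
        if (length(cands) == 0) next
        cd <- unique(rbindlist(cands), by = c("chrom", "pos", "strand"))
        gsub36 <- substring(chromStr[cd$chrom], cd$pos, cd$pos + L - 1L)
        mm <- mapply(mmCount, gsub36, cd$read, USE.NAMES = FALSE)
        best <- min(mm)
        if (best > maxMismatch) next
        ib <- which(mm == best)
        if (length(ib) == 1L) {
          out$status[i] <- "unique"
          out$chrom[i] <- cd$chrom[ib]
          out$pos[i] <- cd$pos[ib]
          out$strand[i] <- cd$strand[ib]
          out$mapq[i] <- if (best == 0L) 37L else 25L
          out$mismatches[i] <- best
        } else out$status[i] <- "multi"
      }
    }
  }
  # orient sequence and qualities to the reference strand
  neg <- which(out$strand == "-")
  if (length(neg) > 0) {
    out$seq[neg] <- .revcompChar(out$seq[neg])
    out$qual[neg] <- vapply(strsplit(out$qual[neg], ""),
                            function(x) paste(rev(x), collapse = ""), "")
  }
  out
}

#' Keep only uniquely mapped alignments
#'
#' @param alignments Output of [mapReads()] or [readSamAlignments()].
#' @return The `unique`-status rows.
#' @export
uniqueAlignments <- function(alignments) {
  alignments[alignments$status == "unique" & !is.na(alignments$chrom), ,
             drop = FALSE]
}

#' Write alignments as SAM
#'
#' Emits a minimal single-end SAM (header + `<L>M` CIGAR records) for the
#' uniquely mapped reads.
#'
#' @param alignments `data.frame` from [mapReads()] (unique rows are
#'   written).
#' @param seqlengths Named integer vector of reference lengths.
#' @param file SAM path.
#' @return The file path, invisibly.
#' @export
writeSamAlignments <- function(alignments, seqlengths, file) {
  aln <- uniqueAlignments(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                 aln$qname, flag, aln$chrom, aln$pos, aln$mapq,
                 nchar(aln$seq), aln$seq, aln$qual)
  writeLines(c(hdr, rec), file)
  invisible(file)
}

#' Read alignments from SAM
#'
#' Ingests a SAM file through Rsamtools (SAM -> BAM -> records) and returns
#' the same alignment table shape that [mapReads()] produces, using the
#' file's own MAPQ values. Unmapped records are dropped.
#'
#' @param file SAM path.
#' @return `data.frame` with columns `qname`, `status`, `chrom`, `pos`,
#'   `strand`, `mapq`, `seq`, `qual`.
#' @export
readSamAlignments <- function(file) {
  bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "strand",
                                        "mapq", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  ok <- !is.na(x$pos)
  data.frame(qname = x$qname[ok], status = "unique",
             chrom = as.character(x$rname)[ok], pos = x$pos[ok],
             strand = as.character(x$strand)[ok], mapq = x$mapq[ok],
             mismatches = NA_integer_,
             seq = as.character(x$seq)[ok], qual = as.character(x$qual)[ok],
             stringsAsFactors = FALSE)
}
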