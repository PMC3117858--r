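#' Per-read quality filters
#'
#' Vectorized keep/drop verdicts for the pre-alignment read filters used in
#' RRL SNP discovery:
#' \describe{
#'   \item{`filterMeanQuality()`}{drop when the arithmetic mean Phred
#'     quality is strictly below `minMean` (default 12).}
#'   \item{`filterStartMotif()`}{drop when the first bases are not the
#'     enzyme's residual motif (default `"CT"`, the 3' half of AluI's
#'     AG^CT site; comparison is case-insensitive, `N` never matches).}
#'   \item{`filterHomopolymer()`}{drop when the longest single-base run
#'     exceeds `maxRun` (default 17 for 36 bp reads, i.e. a run of 18 or
#'     more, >= half the read length, marks likely repeat-derived reads;
#'     `N` breaks runs).}
#' }
#' Each filter is pure: verdicts do not depend on the other filters.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (or, for the
#'   sequence-only filters, any `DNAStringSet`).
#' @param minMean,motif,maxRun Filter thresholds, see above.
#' @return Logical vector, `TRUE` = keep.
#' @export
filterMeanQuality <- function(reads, minMean = 12) {
  q <- as(Biostrings::quality(reads), "matrix")
  rowMeans(q, na.rm = TRUE) >= minMean
}

#' @rdname filterMeanQuality
#' @export
filterStartMotif <- function(reads, motif = "CT") {
  s <- toupper(substr(as.character(reads), 1L, nchar(motif)))
  s == toupper(motif)
}

#' @rdname filterMeanQuality
#' @export
filterHomopolymer <- function(reads, maxRun = 17) {
  k <- maxRun + 1L
  pat <- paste(sprintf("%s{%d,}", c("A", "C", "G", "T"), k), collapse = "|")
  !grepl(pat, as.character(reads))
}

#' Run the per-read QC filters with first-failure accounting
#'
#' Applies mean-quality, start-motif and homopolymer filters in that fixed
#' order; each dropped read is attributed to the first filter it failed, so
#' the report conserves counts.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param minMean,motif,maxRun Thresholds, see [filterMeanQuality()].
#' @param applyMotif Whether to apply the start-motif filter (both mates of
#'   a blunt-cut RRL fragment start with the residual motif on their own
#'   strand, so the default applies it to every read).
#' @return `list(reads, report)`: the retained reads and a
#'   [QcReport-class].
#' @export
runReadQc <- function(reads, minMean = 12, motif = "CT", maxRun = 17,
                      applyMotif = TRUE) {
  n <- length(reads)
  okQ <- filterMeanQuality(reads, minMean)
  okM <- if (applyMotif) filterStartMotif(reads, motif) else rep(TRUE, n)
  okH <- filterHomopolymer(reads, maxRun)
  firstFail <- rep(NA_character_, n)
  firstFail[!okH] <- "homopolymer"
  firstFail[!okM] <- "start_motif"
  firstFail[!okQ] <- "mean_quality"   # highest precedence last
  keep <- is.na(firstFail)
  removed <- table(factor(firstFail,
                          levels = c("mean_quality", "start_motif",
                                     "homopolymer")))
  report <- new("QcReport", inputCount = n,
                removedBy = stats::setNames(as.integer(removed),
                                            names(removed)),
                retainedCount = sum(keep))
  list(reads = reads[keep], report = report)
}

#' Serialize a QcReport as JSON
#'
#' @param report A [QcReport-class].
#' @param file JSON path.
#' @return `readQcReport()` returns a [QcReport-class].
#' @export
writeQcReport <- function(report, file) {
  jsonlite::write_json(list(input_count = report@inputCount,
                            removed_by = as.list(report@removedBy),
                            retained_count = report@retainedCount),
                       file, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeQcReport
#' @export
readQcReport <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("QcReport", inputCount = as.integer(x$input_count),
      removedBy = stats::setNames(as.integer(unlist(x$removed_by)),
                                  names(x$removed_by)),
      retainedCount = as.integer(x$retained_count))
}

#' Estimate mean aligned depth
#'
#' Total aligned bases divided by the number of reference bases covered at
#' least once.
#'
#' @param alignments `data.frame` with columns `chrom`, `pos`, `seq` (as
#'   returned by [mapReads()]; width taken from `seq`).
#' @return Mean fold depth over covered bases.
#' @export
estimateMeanDepth <- function(alignments) {
  if (nrow(alignments) == 0) return(0)
  w <- nchar(alignments$seq)
  covered <- sum(vapply(split(seq_len(nrow(alignments)), alignments$chrom),
    function(i) sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(alignments$pos[i], width = w[i])))), numeric(1)))
  sum(w) / covered
}

#' Remove reads at over-represented alignment start sites
#'
#' A "site" is the (chromosome, start, strand) alignment key — in an RRL
#' library reads stack at restriction cut sites, so start-position
#' multiplicity is the natural unit. All reads at sites observed strictly
#' more than `factor` times the mean depth are removed (likely collapsed
#' repeats).
#'
#' @param alignments `data.frame` with columns `chrom`, `pos`, `strand`
#'   (plus anything else, carried through).
#' @param meanDepth Estimated mean aligned depth; `NULL` (default) estimates
#'   it with [estimateMeanDepth()].
#' @param factor Multiplier (default 5).
#' @return `list(alignments, removedCount, removedSites)`.
#' @export
filterOverrepresentedSites <- function(alignments, meanDepth = NULL,
                                       factor = 5) {
  if (is.null(meanDepth)) meanDepth <- estimateMeanDepth(alignments)
  if (meanDepth <= 0) stop("meanDepth must be > 0")
  dt <- as.data.table(alignments[, c("chrom", "pos", "strand")])
  dt[, site_n := .N, by = .(chrom, pos, strand)]
  drop <- dt$site_n > factor * meanDepth
  removedSites <- unique(alignments[drop, c("chrom", "pos", "strand")])
  list(alignments = alignments[!drop, , drop = FALSE],
       removedCount = sum(drop),
       removedSites = removedSites)
}
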