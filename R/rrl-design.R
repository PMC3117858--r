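#' In-silico restriction digestion
#'
#' Places a cut at every exact occurrence of the recognition site,
#' `cutOffset` bases into the site, and returns the resulting fragment
#' inventory. Matching the forward strand suffices for palindromic sites
#' such as AluI's AG^CT; for non-palindromic enzymes the reverse-complement
#' site is matched as well and its cut mapped back to the forward strand
#' (blunt single-boundary model). Overlapping occurrences are scanned
#' left-to-right and every exact match cuts.
#'
#' @param genome A [SyntheticGenome-class] or named `DNAStringSet`.
#' @param enzyme A [RestrictionEnzyme-class]; default [aluI()].
#' @return A [FragmentInventory-class] whose fragments tile each chromosome.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrT = "GGAGCTTTAGCTAA"))
#' fragments(digestGenome(g))  # widths 4, 6, 4
#' @export
digestGenome <- function(genome, enzyme = aluI()) {
  seqs <- if (is(genome, "SyntheticGenome")) genomeSequences(genome) else genome
  stopifnot(is(seqs, "DNAStringSet"))
  if (length(seqs) == 0) stop("genome is empty")
  if (nchar(enzyme@site) == 0) stop("empty recognition site")
  site <- enzyme@site
  off <- enzyme@cutOffset
  rcsite <- .revcompChar(site)
  perChrom <- lapply(seq_along(seqs), function(i) {
    L <- Biostrings::width(seqs)[i]
    hits <- Biostrings::matchPattern(site, seqs[[i]])
    # boundary b: cut falls between positions b and b+1 (1-based)
    cuts <- Biostrings::start(hits) + off - 1L
    if (rcsite != site) {
      rhits <- Biostrings::matchPattern(rcsite, seqs[[i]])
      cuts <- c(cuts, Biostrings::start(rhits) + (nchar(site) - off) - 1L)
    }
    cuts <- sort(unique(cuts[cuts >= 1L & cuts <= L - 1L]))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    IRanges::IRanges(starts, ends)
  })
  counts <- vapply(perChrom, length, integer(1))
  gr <- GenomicRanges::GRanges(
    rep(names(seqs), counts),
    do.call(c, perChrom),
    seqlengths = stats::setNames(Biostrings::width(seqs), names(seqs)))
  new("FragmentInventory", fragments = gr)
}

#' Fragment lengths and their histogram
#'
#' @param inventory A [FragmentInventory-class].
#' @param breaks Passed to [graphics::hist()]-style binning via `cut()`;
#'   default 25 bp bins up to 1 kb with an overflow bin.
#' @return `fragmentLengths()`: integer vector; `fragmentLengthHistogram()`:
#'   `data.frame` of bin and count.
#' @export
fragmentLengths <- function(inventory) {
  IRanges::width(fragments(inventory))
}

#' @rdname fragmentLengths
#' @export
fragmentLengthHistogram <- function(inventory,
                                    breaks = c(seq(0, 1000, by = 25), Inf)) {
  w <- fragmentLengths(inventory)
  bin <- cut(w, breaks = breaks, include.lowest = TRUE)
  out <- as.data.frame(table(bin), stringsAsFactors = FALSE)
  names(out) <- c("bin", "count")
  out
}

#' Fragment size-selection window
#'
#' Inclusive length bounds emulating gel excision of a size range.
#' The defaults (125-200 bp) are the windows used for RRL construction.
#'
#' @param minBp,maxBp Inclusive bounds, `0 < minBp <= maxBp`.
#' @return A list with class `SizeWindow`.
#' @export
sizeWindow <- function(minBp = 125, maxBp = 200) {
  if (minBp <= 0 || minBp > maxBp)
    stop("require 0 < minBp <= maxBp")
  structure(list(minBp = minBp, maxBp = maxBp), class = "SizeWindow")
}

#' Select the sequenced genome fraction
#'
#' Keeps every fragment whose length lies inside the inclusive window and
#' reports the selected base count and the fraction of the genome it
#' represents (the "reduced representation").
#'
#' @param inventory A [FragmentInventory-class].
#' @param window A [sizeWindow()].
#' @return `list(fragments, selectedBp, fraction)` where `fragments` is a
#'   `GRanges` of the kept fragments.
#' @export
selectFraction <- function(inventory, window = sizeWindow()) {
  gr <- fragments(inventory)
  w <- IRanges::width(gr)
  keep <- w >= window$minBp & w <= window$maxBp
  sel <- gr[keep]
  totalBp <- sum(as.numeric(GenomeInfoDb::seqlengths(gr)))
  selectedBp <- sum(as.numeric(IRanges::width(sel)))
  list(fragments = sel, selectedBp = selectedBp,
       fraction = selectedBp / totalBp)
}

#' Expected sequencing depth over the selected fraction
#'
#' `depth = total sequenced bases / selected bases`: the fold-coverage of
#' the reduced representation, the arithmetic linking genome coverage and
#' sequence depth in an RRL design.
#'
#' @param selectedBp Selected bases (> 0).
#' @param totalSequencedBp Total sequenced bases landing on the selection.
#' @return Fold depth (numeric).
#' @export
expectedDepth <- function(selectedBp, totalSequencedBp) {
  if (selectedBp <= 0) stop("selectedBp must be > 0")
  totalSequencedBp / selectedBp
}

#' BED round-trip for fragment sets
#'
#' Writes fragments as 0-based half-open BED via rtracklayer and reads them
#' back as 1-based `GRanges`.
#'
#' @param x A `GRanges` (e.g. `fragments(inventory)` or a selected set).
#' @param file BED path.
#' @return `readFragmentsBed()` returns a `GRanges`.
#' @export
writeFragmentsBed <- function(x, file) {
  if (is(x, "FragmentInventory")) x <- fragments(x)
  rtracklayer::export(x, file, format = "BED")
  invisible(file)
}

#' @rdname writeFragmentsBed
#' @export
readFragmentsBed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  S4Vectors::mcols(gr) <- NULL
  gr
}
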