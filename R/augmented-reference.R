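#' Augment an assembly with unplaced contigs
#'
#' Concatenates every contig at or above `minContigBp` into one artificial
#' chromosome, with runs of N bases as spacers between contigs, and appends
#' it to the assembly. This lets reads from sequence absent from the
#' assembly be mapped and their SNPs called; the offset table keeps the
#' artificial coordinates invertible.
#'
#' @param assembly Named `DNAStringSet` (or [SyntheticGenome-class]) of
#'   assembly chromosomes.
#' @param contigs Named `DNAStringSet` of contigs; ids must be unique.
#' @param minContigBp Minimum contig length kept (default 200 bp).
#' @param spacerLen Spacer length between consecutive contigs (default 100;
#'   longer than a read so no read spans two contigs).
#' @param artificialName Name for the artificial chromosome.
#' @return An [AugmentedReference-class]. With no kept contig the
#'   artificial chromosome is absent.
#' @export
buildAugmentedReference <- function(assembly, contigs, minContigBp = 200,
                                    spacerLen = 100,
                                    artificialName = "chrArtificial") {
  if (is(assembly, "SyntheticGenome")) assembly <- genomeSequences(assembly)
  if (is(contigs, "SyntheticGenome")) contigs <- genomeSequences(contigs)
  if (length(contigs) > 0 &&
      (is.null(names(contigs)) || anyDuplicated(names(contigs))))
    stop("duplicate contig id")
  keep <- contigs[Biostrings::width(contigs) >= minContigBp]
  if (length(keep) == 0)
    return(new("AugmentedReference", genome = assembly,
               offsets = data.frame(contig = character(), start = integer(),
                                    width = integer()),
               artificialName = artificialName,
               spacerLen = as.integer(spacerLen)))
  w <- Biostrings::width(keep)
  starts <- cumsum(c(1L, head(w + spacerLen, -1L)))
  spacer <- strrep("N", spacerLen)
  art <- paste(as.character(keep), collapse = spacer)
  genome <- c(assembly, Biostrings::DNAStringSet(stats::setNames(art,
                                                  artificialName)))
  new("AugmentedReference", genome = genome,
      offsets = data.frame(contig = names(keep), start = starts, width = w,
                           stringsAsFactors = FALSE),
      artificialName = artificialName, spacerLen = as.integer(spacerLen))
}

#' Map between contig and artificial-chromosome coordinates
#'
#' `contigToArtificial()` converts a (contig, position) pair to a position
#' on the artificial chromosome; `artificialToContig()` inverts it.
#' Positions falling inside spacer runs map to no contig (`NA`).
#'
#' @param ref An [AugmentedReference-class].
#' @param contig Contig id(s).
#' @param pos 1-based position(s), on the contig or on the artificial
#'   chromosome respectively.
#' @return `contigToArtificial()`: integer positions.
#'   `artificialToContig()`: `data.frame` with columns `contig`, `pos`
#'   (`NA` rows for spacer positions).
#' @export
contigToArtificial <- function(ref, contig, pos) {
  i <- match(contig, ref@offsets$contig)
  if (anyNA(i)) stop("unknown contig id")
  if (any(pos < 1L | pos > ref@offsets$width[i]))
    stop("position outside contig")
  ref@offsets$start[i] + as.integer(pos) - 1L
}

#' @rdname contigToArtificial
#' @export
artificialToContig <- function(ref, pos) {
  off <- ref@offsets
  out <- data.frame(contig = rep(NA_character_, length(pos)),
                    pos = rep(NA_integer_, length(pos)))
  if (nrow(off) == 0) return(out)
  i <- findInterval(pos, off$start)
  ok <- i >= 1L & pos <= off$start[pmax(i, 1L)] + off$width[pmax(i, 1L)] - 1L
  out$contig[ok] <- off$contig[i[ok]]
  out$pos[ok] <- as.integer(pos[ok] - off$start[i[ok]] + 1L)
  out
}

#' Spacer mask of the artificial chromosome
#'
#' @param ref An [AugmentedReference-class].
#' @return `GRanges` of spacer runs on the artificial chromosome (empty when
#'   no contigs were kept).
#' @keywords internal
.spacerRanges <- function(ref) {
  off <- ref@offsets
  if (nrow(off) < 2L)
    return(GenomicRanges::GRanges())
  s <- off$start[-nrow(off)] + off$width[-nrow(off)]
  GenomicRanges::GRanges(ref@artificialName,
                         IRanges::IRanges(s, width = ref@spacerLen))
}
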