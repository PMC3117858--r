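#' @importClassesFrom Biostrings DNAStringSet QualityScaledDNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

.SIZE_CLASSES <- c("macro", "intermediate", "micro", "unplaced_contig", "mito")

#' Synthetic genome with chromosome size classes
#'
#' Holds a set of chromosome sequences together with a size-class label per
#' chromosome. The size classes mirror avian genome architecture: a few large
#' macro-chromosomes, intermediate chromosomes, many small gene-dense
#' micro-chromosomes, unplaced contigs and the mitochondrial genome.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of chromosome sequences
#'   (unique names required; alphabet restricted to A, C, G, T, N).
#' @slot sizeClass Character vector parallel to `sequences`, each element one
#'   of `"macro"`, `"intermediate"`, `"micro"`, `"unplaced_contig"`, `"mito"`.
#'
#' @seealso [generateGenome()]
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
         slots = c(sequences = "DNAStringSet", sizeClass = "character"))

setValidity("SyntheticGenome", function(object) {
  seqs <- object@sequences
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm))
    return("chromosome names must be present and unique")
  if (length(object@sizeClass) != length(seqs))
    return("sizeClass must have one entry per chromosome")
  if (!all(object@sizeClass %in% .SIZE_CLASSES))
    return(paste("sizeClass values must be in:",
                 paste(.SIZE_CLASSES, collapse = ", ")))
  af <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(af[, !(colnames(af) %in% allowed), drop = FALSE])
  if (any(bad > 0)) return("sequences may only contain A, C, G, T, N")
  TRUE
})

#' Construct a SyntheticGenome
#'
#' @param sequences A named [Biostrings::DNAStringSet].
#' @param sizeClass Character vector of size classes, one per chromosome
#'   (recycled names from `sequences` if unnamed).
#' @return A [SyntheticGenome-class] object.
#' @export
SyntheticGenome <- function(sequences, sizeClass) {
  sizeClass <- unname(sizeClass[if (!is.null(names(sizeClass)))
    names(sequences) else seq_along(sequences)])
  new("SyntheticGenome", sequences = sequences, sizeClass = sizeClass)
}

#' Restriction enzyme description
#'
#' @slot name Enzyme name.
#' @slot site Recognition site (IUPAC not supported; exact DNA string).
#' @slot cutOffset Cut position within the site: the enzyme cuts after
#'   `cutOffset` bases of the site (0 = before the site, `nchar(site)` =
#'   after it). AluI is `AG^CT`: site `"AGCT"`, offset 2, blunt.
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
         slots = c(name = "character", site = "character",
                   cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  if (!.isSingleString(object@site) || nchar(object@site) == 0)
    return("recognition site must be a nonempty DNA string")
  if (!grepl("^[ACGT]+$", object@site))
    return("recognition site must be over A, C, G, T")
  if (object@cutOffset < 0L || object@cutOffset > nchar(object@site))
    return("cutOffset must lie within the recognition site")
  TRUE
})

#' @rdname RestrictionEnzyme-class
#' @param name,site,cutOffset See slot descriptions.
#' @return A `RestrictionEnzyme` object.
#' @export
restrictionEnzyme <- function(name, site, cutOffset) {
  new("RestrictionEnzyme", name = name, site = toupper(site),
      cutOffset = as.integer(cutOffset))
}

#' @rdname RestrictionEnzyme-class
#' @details `aluI()` returns the default enzyme used throughout: AluI,
#'   a blunt four-cutter (`AG^CT`).
#' @export
aluI <- function() restrictionEnzyme("AluI", "AGCT", 2L)

#' Restriction fragment inventory
#'
#' The complete set of restriction fragments of a genome, one
#' [GenomicRanges::GRanges] whose ranges exactly tile every chromosome:
#' the first fragment starts at 1, adjacent fragments abut, and the last
#' fragment ends at the chromosome length.
#'
#' @slot fragments A `GRanges` with `seqlengths` set.
#' @seealso [digestGenome()], [selectFraction()]
#' @exportClass FragmentInventory
setClass("FragmentInventory", slots = c(fragments = "GRanges"))

setValidity("FragmentInventory", function(object) {
  gr <- object@fragments
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) return("seqlengths must be set for all chromosomes")
  for (chr in GenomeInfoDb::seqlevels(gr)) {
    r <- IRanges::ranges(gr[GenomicRanges::seqnames(gr) == chr])
    if (length(r) == 0L) next
    r <- IRanges::ranges(sort(gr[GenomicRanges::seqnames(gr) == chr]))
    if (IRanges::start(r)[1] != 1L)
      return(sprintf("fragments on %s do not start at 1", chr))
    if (IRanges::end(r)[length(r)] != sl[[chr]])
      return(sprintf("fragments on %s do not end at the chromosome end", chr))
    if (length(r) > 1L &&
        !all(IRanges::start(r)[-1] == IRanges::end(r)[-length(r)] + 1L))
      return(sprintf("fragments on %s do not abut", chr))
    if (any(IRanges::width(r) < 1L))
      return("fragment widths must be >= 1")
  }
  TRUE
})

#' Reference genome augmented with an artificial contig chromosome
#'
#' An assembly plus one artificial chromosome built by concatenating
#' unplaced contigs at or above a length threshold, separated by N spacers.
#' The offset table makes every contig base recoverable from its position on
#' the artificial chromosome and vice versa.
#'
#' @slot genome `DNAStringSet`: assembly chromosomes, plus the artificial
#'   chromosome when at least one contig was kept.
#' @slot offsets `data.frame` with columns `contig`, `start` (1-based start
#'   on the artificial chromosome) and `width`.
#' @slot artificialName Name of the artificial chromosome.
#' @slot spacerLen Number of N bases between consecutive contigs.
#' @seealso [buildAugmentedReference()]
#' @exportClass AugmentedReference
setClass("AugmentedReference",
         slots = c(genome = "DNAStringSet", offsets = "data.frame",
                   artificialName = "character", spacerLen = "integer"))

setValidity("AugmentedReference", function(object) {
  off <- object@offsets
  if (nrow(off) > 0) {
    if (anyDuplicated(off$contig)) return("duplicate contig ids")
    if (!(object@artificialName %in% names(object@genome)))
      return("artificial chromosome missing from genome")
    L <- length(object@genome[[object@artificialName]])
    if (any(off$start + off$width - 1L > L))
      return("offset table exceeds artificial chromosome length")
  }
  TRUE
})

#' Read-filtering report
#'
#' Per-filter accounting for a QC run. Each dropped read is attributed to
#' the first filter it failed, so counts conserve:
#' `inputCount == retainedCount + sum(removedBy)`.
#'
#' @slot inputCount Number of reads in.
#' @slot removedBy Named integer vector of drop counts per filter.
#' @slot retainedCount Number of reads retained.
#' @seealso [runReadQc()]
#' @exportClass QcReport
setClass("QcReport",
         slots = c(inputCount = "integer", removedBy = "integer",
                   retainedCount = "integer"))

setValidity("QcReport", function(object) {
  if (object@inputCount != object@retainedCount + sum(object@removedBy))
    return("inputCount must equal retainedCount + sum(removedBy)")
  if (is.null(names(object@removedBy)))
    return("removedBy must be named by filter")
  TRUE
})

.PANEL_CATEGORIES <- c("chromosome_selected", "unplaced_contig",
                       "chr_random", "mito")

#' Selected array content
#'
#' The SNPs selected for the array, with a provenance category per SNP
#' (`chromosome_selected` for the spacing-driven chromosome walk, plus the
#' fixed add-on sets `unplaced_contig`, `chr_random` and `mito`).
#'
#' @slot snps `data.frame` with at least columns `id`, `chrom`, `pos`,
#'   `category`; typically also `alleles`, `class` and `source`.
#' @seealso [assembleManifest()], [categoryCounts()]
#' @exportClass PanelManifest
setClass("PanelManifest", slots = c(snps = "data.frame"))

setValidity("PanelManifest", function(object) {
  s <- object@snps
  need <- c("id", "chrom", "pos", "category")
  if (!all(need %in% names(s)))
    return(paste("manifest needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$id)) return("duplicate SNP ids in manifest")
  if (!all(s$category %in% .PANEL_CATEGORIES))
    return("invalid provenance category")
  TRUE
})

#' Simulated array genotype calls
#'
#' Genotypes for a breed panel over the SNPs of a manifest, with per-SNP
#' assay status (design success) and clustering status, as produced by
#' [simulateAssay()]. Calls are `"AA"`, `"AB"`, `"BB"` or `NA` (missing);
#' SNPs that failed assay design carry no calls.
#'
#' @slot calls Character matrix, samples x SNPs.
#' @slot breed Breed label per sample (rows of `calls`).
#' @slot assayStatus Per SNP: `"designed"` or `"failed_design"`.
#' @slot clusterOk Per SNP: `FALSE` when genotype clustering failed.
#' @exportClass GenotypeCallSet
setClass("GenotypeCallSet",
         slots = c(calls = "matrix", breed = "character",
                   assayStatus = "character", clusterOk = "logical"))

setValidity("GenotypeCallSet", function(object) {
  if (nrow(object@calls) != length(object@breed))
    return("one breed label per sample row required")
  if (ncol(object@calls) != length(object@assayStatus) ||
      ncol(object@calls) != length(object@clusterOk))
    return("assayStatus and clusterOk must have one entry per SNP")
  if (!all(object@assayStatus %in% c("designed", "failed_design")))
    return("assayStatus must be 'designed' or 'failed_design'")
  failed <- object@assayStatus == "failed_design"
  if (any(failed) && any(!is.na(object@calls[, failed, drop = FALSE])))
    return("failed_design SNPs must have no calls")
  ok <- object@calls %in% c("AA", "AB", "BB") | is.na(object@calls)
  if (!all(ok)) return("calls must be AA, AB, BB or NA")
  TRUE
})
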