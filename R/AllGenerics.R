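#' Accessors for package classes
#'
#' `genomeSequences()` returns the chromosome sequences of a
#' [SyntheticGenome-class] (or the genome of an [AugmentedReference-class]);
#' `sizeClass()` the per-chromosome size-class labels; `totalBp()` the summed
#' chromosome lengths; `fragments()` the fragment ranges of a
#' [FragmentInventory-class]; `categoryCounts()` the per-provenance-category
#' SNP counts of a [PanelManifest-class]; `manifestSnps()` its SNP table.
#'
#' @param x An object of the documented class.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))

#' @rdname accessors
#' @export
setGeneric("sizeClass", function(x) standardGeneric("sizeClass"))

#' @rdname accessors
#' @export
setGeneric("totalBp", function(x) standardGeneric("totalBp"))

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname accessors
#' @export
setGeneric("manifestSnps", function(x) standardGeneric("manifestSnps"))

#' @rdname accessors
#' @export
setMethod("genomeSequences", "SyntheticGenome", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("genomeSequences", "AugmentedReference", function(x) x@genome)

#' @rdname accessors
#' @export
setMethod("sizeClass", "SyntheticGenome",
          function(x) stats::setNames(x@sizeClass, names(x@sequences)))

#' @rdname accessors
#' @export
setMethod("totalBp", "SyntheticGenome",
          function(x) sum(Biostrings::width(x@sequences)))

#' @rdname accessors
#' @export
setMethod("fragments", "FragmentInventory", function(x) x@fragments)

#' @rdname accessors
#' @export
setMethod("manifestSnps", "PanelManifest", function(x) x@snps)

#' @rdname accessors
#' @export
setMethod("categoryCounts", "PanelManifest", function(x) {
  counts <- table(factor(x@snps$category, levels = .PANEL_CATEGORIES))
  stats::setNames(as.integer(counts), names(counts))
})

setMethod("show", "SyntheticGenome", function(object) {
  w <- Biostrings::width(object@sequences)
  cat("SyntheticGenome:", length(w), "chromosome(s),",
      format(sum(w), big.mark = ","), "bp\n")
  cls <- table(object@sizeClass)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
})

setMethod("show", "RestrictionEnzyme", function(object) {
  site <- object@site
  cat(sprintf("RestrictionEnzyme %s: %s^%s\n", object@name,
              substr(site, 1, object@cutOffset),
              substr(site, object@cutOffset + 1, nchar(site))))
})

setMethod("show", "FragmentInventory", function(object) {
  w <- IRanges::width(object@fragments)
  cat("FragmentInventory:", length(w), "fragments on",
      length(GenomeInfoDb::seqlevels(object@fragments)), "chromosome(s)\n")
  cat("  length range:", min(w), "-", max(w), "bp; median", median(w), "bp\n")
})

setMethod("show", "AugmentedReference", function(object) {
  cat("AugmentedReference:", length(object@genome), "sequence(s)\n")
  if (nrow(object@offsets) > 0)
    cat("  artificial chromosome", object@artificialName, "holds",
        nrow(object@offsets), "contig(s), spacer", object@spacerLen, "bp\n")
  else cat("  no contigs kept; artificial chromosome absent\n")
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport:", object@inputCount, "reads in,",
      object@retainedCount, "retained\n")
  for (f in names(object@removedBy))
    cat(sprintf("  removed by %s: %d\n", f, object@removedBy[[f]]))
})

setMethod("show", "PanelManifest", function(object) {
  cc <- categoryCounts(object)
  cat("PanelManifest:", nrow(object@snps), "SNPs\n")
  for (k in names(cc)) cat(sprintf("  %s: %d\n", k, cc[[k]]))
})

setMethod("show", "GenotypeCallSet", function(object) {
  cat("GenotypeCallSet:", nrow(object@calls), "samples x",
      ncol(object@calls), "SNPs;",
      sum(object@assayStatus == "failed_design"), "failed design\n")
})
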