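#' Build a candidate table from merged SNP calls
#'
#' Bridges discovery and panel design: converts a [mergePopulations()]
#' result into the candidate `data.frame` the panel-design functions
#' consume, computing Infinium type from the allele pair, group MAFs as
#' the mean of the per-population MAF estimates within the broiler and
#' layer groups, the neighbour-exclusion flag against the full variant set,
#' and attaching design scores.
#'
#' @param merged `merged` data.frame from [mergePopulations()]
#'   (non-conflicting rows are used).
#' @param designScores Named numeric from [assignDesignScores()]; names are
#'   `chrom:pos` ids.
#' @param broilerPops,layerPops Population ids making up each group.
#' @param validatedIds Ids of SNPs previously assayed successfully.
#' @param windowBp Neighbour window (default 10 bp).
#' @return Candidate `data.frame` with columns `id`, `chrom`, `pos`,
#'   `allele1`, `allele2`, `infinium_type`, `design_score`, `validated`,
#'   `source`, `maf_broiler`, `maf_layer`, `neighbor_excluded`.
#' @export
buildCandidateTable <- function(merged, designScores,
                                broilerPops = c("B1", "B2"),
                                layerPops = c("BL", "WL"),
                                validatedIds = character(),
                                windowBp = 10) {
  m <- merged[!merged$conflict, , drop = FALSE]
  id <- paste0(m$chrom, ":", m$pos)
  groupMaf <- function(pops) {
    cols <- paste0("maf_", pops)
    cols <- cols[cols %in% names(m)]
    if (length(cols) == 0) return(rep(NA_real_, nrow(m)))
    v <- rowMeans(as.matrix(m[, cols, drop = FALSE]), na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }
  out <- data.frame(
    id = id, chrom = m$chrom, pos = m$pos,
    allele1 = m$ref, allele2 = m$alt,
    infinium_type = classifyInfinium(m$ref, m$alt),
    design_score = unname(designScores[id]),
    validated = id %in% validatedIds,
    source = ifelse(m$known_flag, "rrl_and_db", "rrl_novel"),
    maf_broiler = groupMaf(broilerPops),
    maf_layer = groupMaf(layerPops),
    stringsAsFactors = FALSE)
  out$neighbor_excluded <- flagNeighbors(out, out[, c("chrom", "pos")],
                                         windowBp = windowBp)
  out
}
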