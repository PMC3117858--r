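#' Infinium assay type of an allele pair
#'
#' Type II SNPs (A/C, A/G, T/C, T/G) need a single bead type on the array;
#' the complement-ambiguous pairs A/T and C/G are type I and need two.
#'
#' @param allele1,allele2 Base vectors (unordered pair per SNP; must
#'   differ).
#' @return Character vector of `"I"` / `"II"`.
#' @examples
#' classifyInfinium("A", "G")  # "II"
#' classifyInfinium("A", "T")  # "I"
#' @export
classifyInfinium <- function(allele1, allele2) {
  a <- toupper(allele1); b <- toupper(allele2)
  if (any(a == b)) stop("alleles must be distinct")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("alleles must be single bases")
  typeI <- (pmin(a, b) == "A" & pmax(a, b) == "T") |
           (pmin(a, b) == "C" & pmax(a, b) == "G")
  ifelse(typeI, "I", "II")
}

#' Flag SNPs with close neighbouring variants
#'
#' A SNP with another variant within `windowBp` of it (same chromosome,
#' excluding itself) risks probe failure; such candidates are excluded from
#' panel selection.
#'
#' @param candidates `data.frame` with `id`, `chrom`, `pos`.
#' @param allVariants `data.frame` with `chrom`, `pos` of every known
#'   variant (typically a superset of the candidates).
#' @param windowBp Window half-width in bp (default 10).
#' @return Logical vector parallel to `candidates`: `TRUE` when a distinct
#'   variant lies within the window.
#' @export
flagNeighbors <- function(candidates, allVariants, windowBp = 10) {
  cn <- GenomicRanges::GRanges(candidates$chrom,
          IRanges::IRanges(pmax(1L, candidates$pos - windowBp),
                           candidates$pos + windowBp))
  va <- GenomicRanges::GRanges(allVariants$chrom,
          IRanges::IRanges(allVariants$pos, width = 1))
  hits <- GenomicRanges::countOverlaps(cn, va)
  # subtract the self-match (a variant at the candidate's own position)
  self <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(candidates$chrom,
                           IRanges::IRanges(candidates$pos, width = 1)), va)
  (hits - pmin(self, 1L)) > 0
}

#' Default 25-class priority table
#'
#' Priorities are a 5 x 5 lattice: five source/validation levels crossed
#' with five MAF tiers, ordered lexicographically (class 1 highest).
#' Source levels: (1) previously validated in a genotyping assay; (2)
#' RRL-discovered and already in the known-SNP database; (3) RRL-discovered
#' novel SNP with MAF estimates in both broilers and layers; (4)
#' RRL-discovered novel SNP with a MAF estimate in one group; (5)
#' database SNP never assayed, no MAF available. MAF tiers on the mean of
#' the available group MAFs: >= 0.3, 0.2-0.3, 0.1-0.2, 0.05-0.1,
#' < 0.05 or absent. A validated SNP with high MAF in both groups is class
#' 1; a never-assayed database SNP without MAF is class 25.
#'
#' @return `data.frame` with columns `source_level`, `maf_tier`, `class`.
#' @export
defaultPriorityTable <- function() {
  data.frame(source_level = rep(1:5, each = 5),
             maf_tier = rep(1:5, times = 5),
             class = 1:25)
}

.MAF_TIER_BREAKS <- c(0.3, 0.2, 0.1, 0.05)

.mafTier <- function(mafBroiler, mafLayer) {
  m <- rowMeans(cbind(mafBroiler, mafLayer), na.rm = TRUE)
  tier <- rep(5L, length(m))
  has <- !is.nan(m) & !is.na(m)
  tier[has & m >= 0.05] <- 4L
  tier[has & m >= 0.1] <- 3L
  tier[has & m >= 0.2] <- 2L
  tier[has & m >= 0.3] <- 1L
  tier
}

.sourceLevel <- function(validated, source, mafBroiler, mafLayer) {
  hasB <- !is.na(mafBroiler); hasL <- !is.na(mafLayer)
  lvl <- integer(length(validated))
  lvl[validated] <- 1L
  nv <- !validated
  lvl[nv & source == "rrl_and_db"] <- 2L
  lvl[nv & source == "rrl_novel" & hasB & hasL] <- 3L
  lvl[nv & source == "rrl_novel" & !(hasB & hasL)] <- 4L
  lvl[nv & source == "known_db"] <- 5L
  lvl
}

#' Assign priority classes to eligible candidates
#'
#' Candidates must already be eligible (Infinium type II, design score at
#' least 0.6, no close neighbour); ineligible rows are an error. Each
#' candidate lands in exactly one of the 25 classes (the lattice is a
#' partition of the eligible space).
#'
#' @param candidates `data.frame` with columns `validated` (logical),
#'   `source` (`"known_db"`, `"rrl_novel"`, `"rrl_and_db"`), `maf_broiler`,
#'   `maf_layer` (numeric or `NA`), plus eligibility columns
#'   `infinium_type`, `design_score`, `neighbor_excluded` when present.
#' @param table Priority table (see [defaultPriorityTable()]).
#' @param minScore Design-score eligibility threshold (default 0.6).
#' @return Integer vector of classes, 1 (highest) to 25 (lowest).
#' @export
assignPriority <- function(candidates, table = defaultPriorityTable(),
                           minScore = 0.6) {
  if (!is.null(candidates$infinium_type) &&
      any(candidates$infinium_type != "II"))
    stop("ineligible candidate: Infinium type I")
  if (!is.null(candidates$design_score) &&
      any(candidates$design_score < minScore))
    stop("ineligible candidate: design score below threshold")
  if (!is.null(candidates$neighbor_excluded) &&
      any(candidates$neighbor_excluded))
    stop("ineligible candidate: neighbouring variant within window")
  lvl <- .sourceLevel(candidates$validated, candidates$source,
                      candidates$maf_broiler, candidates$maf_layer)
  if (any(lvl == 0L)) stop("candidate matches no source level")
  tier <- .mafTier(candidates$maf_broiler, candidates$maf_layer)
  cls <- table$class[match(paste(lvl, tier),
                           paste(table$source_level, table$maf_tier))]
  if (anyNA(cls)) stop("priority table does not cover the lattice")
  cls
}

#' Filter candidates to the panel-eligible set
#'
#' Eligibility: Infinium type II, design score >= `minScore`, not
#' neighbour-excluded.
#'
#' @param candidates Candidate `data.frame` with `infinium_type`,
#'   `design_score`, `neighbor_excluded`.
#' @param minScore Design-score threshold (default 0.6).
#' @return The eligible subset.
#' @export
eligibleCandidates <- function(candidates, minScore = 0.6) {
  keep <- candidates$infinium_type == "II" &
    candidates$design_score >= minScore & !candidates$neighbor_excluded
  candidates[keep, , drop = FALSE]
}

#' Per-chromosome target spacing plan
#'
#' Macro-chromosomes get `macroBp` between SNPs and micro-chromosomes
#' `microBp` (default 20 kb and 4 kb): recombination per bp is higher on
#' the small chromosomes, so a similar per-cM marker density needs a denser
#' bp spacing there. The intermediate class is log-interpolated (geometric
#' mean) between the two.
#'
#' @param chromTable `data.frame` with columns `name`, `length`, `class`
#'   (classes `macro`, `intermediate`, `micro`).
#' @param macroBp,microBp Spacing anchors in bp.
#' @return `data.frame`: `name`, `length`, `class`, `spacing` (bp).
#' @export
spacingPlan <- function(chromTable, macroBp = 20000, microBp = 4000) {
  stopifnot(all(c("name", "length", "class") %in% names(chromTable)))
  sp <- c(macro = macroBp,
          intermediate = round(sqrt(macroBp * microBp)),
          micro = microBp)
  unknown <- setdiff(chromTable$class, names(sp))
  if (length(unknown) > 0)
    stop("unknown chromosome class: ", paste(unknown, collapse = ", "))
  out <- chromTable[, c("name", "length", "class")]
  out$spacing <- unname(sp[chromTable$class])
  out
}

#' Greedy scroll-and-select panel builder
#'
#' Walks along each chromosome keeping a cursor at the last selected
#' position. At each step the candidate window is
#' `(cursor + spacing/2, cursor + 3*spacing/2]`; the best candidate in the
#' window is selected — lowest priority class, ties broken by higher mean
#' MAF, then leftmost position — and the cursor moves to it. An empty
#' window advances the cursor by `spacing` and records a gap. Deterministic
#' for identical input.
#'
#' @param candidates Eligible candidate `data.frame` with `id`, `chrom`,
#'   `pos`, `class` (from [assignPriority()]) and optionally `maf_broiler`,
#'   `maf_layer`.
#' @param plan Spacing plan from [spacingPlan()].
#' @return `data.frame` of selected candidates (columns of `candidates`),
#'   with a `data.frame` attribute `"gaps"` (`chrom`, `cursor`) recording
#'   windows with no candidate.
#' @export
selectPanel <- function(candidates, plan) {
  stopifnot(all(c("id", "chrom", "pos", "class") %in% names(candidates)))
  mafMean <- rowMeans(cbind(candidates$maf_broiler, candidates$maf_layer),
                      na.rm = TRUE)
  mafMean[is.nan(mafMean)] <- -Inf
  selected <- integer(0)
  gaps <- list()
  for (k in seq_len(nrow(plan))) {
    chr <- plan$name[k]; spacing <- plan$spacing[k]; len <- plan$length[k]
    idx <- which(candidates$chrom == chr)
    idx <- idx[order(candidates$pos[idx])]
    pos <- candidates$pos[idx]
    cursor <- 0
    while (cursor + spacing / 2 < len) {
      lo <- cursor + spacing / 2      # exclusive
      hi <- cursor + 3 * spacing / 2  # inclusive
      inWin <- idx[pos > lo & pos <= hi]
      if (length(inWin) == 0) {
        gaps[[length(gaps) + 1L]] <- data.frame(chrom = chr, cursor = cursor)
        cursor <- cursor + spacing
      } else {
        o <- order(candidates$class[inWin], -mafMean[inWin],
                   candidates$pos[inWin])
        pick <- inWin[o[1]]
        selected <- c(selected, pick)
        cursor <- candidates$pos[pick]
      }
    }
  }
  out <- candidates[selected, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(chrom = character(), cursor = numeric())
  out
}

#' Assemble the array manifest
#'
#' Combines the chromosome-walk selection with the fixed add-on sets
#' (SNPs on unplaced contigs, on chr_random bins, and mitochondrial SNPs).
#' Add-ons bypass spacing and eligibility — they exist to cover sequence
#' the selection walk cannot reach. Ids must be disjoint across categories.
#'
#' @param chromosomeSelected `data.frame` with at least `id`, `chrom`,
#'   `pos` (output of [selectPanel()]).
#' @param addons Named list of `data.frame`s for categories
#'   `unplaced_contig`, `chr_random`, `mito` (any subset; same columns).
#' @return A [PanelManifest-class].
#' @export
assembleManifest <- function(chromosomeSelected,
                             addons = list()) {
  pieces <- list(cbind(chromosomeSelected,
                       category = "chromosome_selected",
                       stringsAsFactors = FALSE))
  for (nm in names(addons)) {
    if (!nm %in% c("unplaced_contig", "chr_random", "mito"))
      stop("unknown add-on category: ", nm)
    a <- addons[[nm]]
    if (nrow(a) > 0)
      pieces[[length(pieces) + 1L]] <- cbind(a, category = nm,
                                             stringsAsFactors = FALSE)
  }
  common <- Reduce(intersect, lapply(pieces, names))
  snps <- do.call(rbind, lapply(pieces, function(x) x[, common, drop = FALSE]))
  if (anyDuplicated(snps$id)) stop("duplicate id across categories")
  rownames(snps) <- NULL
  new("PanelManifest", snps = snps)
}

#' Write a manifest as TSV
#'
#' @param manifest A [PanelManifest-class].
#' @param file TSV path.
#' @return The path, invisibly.
#' @export
writeManifest <- function(manifest, file) {
  write.table(manifestSnps(manifest), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Adjacent-SNP spacing distribution of a manifest
#'
#' Gaps are computed between consecutive selected SNPs within each
#' chromosome (a chromosome with a single SNP contributes no gap) and
#' histogrammed per chromosome size class.
#'
#' @param manifest A [PanelManifest-class] (only `chromosome_selected`
#'   SNPs enter).
#' @param chromClasses Named character vector mapping chromosome name to
#'   size class.
#' @param breaks Histogram bin edges in bp (default 2 kb bins to 40 kb
#'   plus an overflow bin).
#' @return `list(gaps, histogram)`: `gaps` is a `data.frame` with `chrom`,
#'   `class`, `gap`; `histogram` a class x bin count table.
#' @export
spacingDistribution <- function(manifest, chromClasses,
                                breaks = c(seq(0, 40000, by = 2000), Inf)) {
  s <- manifestSnps(manifest)
  s <- s[s$category == "chromosome_selected", , drop = FALSE]
  gaps <- do.call(rbind, lapply(split(s, s$chrom), function(x) {
    p <- sort(x$pos)
    if (length(p) < 2L) return(NULL)
    data.frame(chrom = x$chrom[1], gap = diff(p), stringsAsFactors = FALSE)
  }))
  if (is.null(gaps))
    gaps <- data.frame(chrom = character(), gap = numeric())
  gaps$class <- unname(chromClasses[gaps$chrom])
  rownames(gaps) <- NULL
  histogram <- table(gaps$class, cut(gaps$gap, breaks = breaks,
                                     include.lowest = TRUE))
  list(gaps = gaps, histogram = histogram)
}
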