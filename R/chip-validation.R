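#' Simulate array genotyping over a breed panel
#'
#' Genotype-level stand-in for the Infinium assay plus genotype clustering:
#' each SNP fails assay design with probability `pFailDesign` (no calls at
#' all); surviving SNPs fail clustering with probability `pClusterFail`
#' (later classified "excluded"); genotypes are drawn in Hardy-Weinberg
#' proportions from the SNP's frequency in each breed, with a small missing
#' rate. The default failure rates match the design-failure (~5%) and
#' exclusion (~2%) rates observed for a commercial 60K chip.
#'
#' @param snpIds Character vector of SNP ids (or a [PanelManifest-class]).
#' @param breedFreqs Numeric matrix, SNPs x breeds: B-allele frequency per
#'   breed. Row names must match the SNP ids; every SNP needs a frequency
#'   in every breed.
#' @param samplesPerBreed Diploid samples per breed (default 24).
#' @param pFailDesign,pClusterFail Failure probabilities.
#' @param missingRate Per-call missing probability (default 0.01).
#' @param seed Optional integer seed.
#' @return A [GenotypeCallSet-class].
#' @export
simulateAssay <- function(snpIds, breedFreqs, samplesPerBreed = 24,
                          pFailDesign = 0.05, pClusterFail = 0.02,
                          missingRate = 0.01, seed = NULL) {
  if (is(snpIds, "PanelManifest")) snpIds <- manifestSnps(snpIds)$id
  stopifnot(is.matrix(breedFreqs), !is.null(colnames(breedFreqs)))
  if (!all(snpIds %in% rownames(breedFreqs)))
    stop("breed without frequencies for some SNPs")
  stopifnot(pFailDesign >= 0, pFailDesign <= 1,
            pClusterFail >= 0, pClusterFail <= 1)
  if (!is.null(seed)) set.seed(seed)
  breeds <- colnames(breedFreqs)
  nS <- length(snpIds)
  breed <- rep(breeds, each = samplesPerBreed)
  nSamp <- length(breed)
  failed <- runif(nS) < pFailDesign
  clusterOk <- runif(nS) >= pClusterFail
  calls <- matrix(NA_character_, nSamp, nS,
                  dimnames = list(NULL, snpIds))
  for (b in breeds) {
    rows <- which(breed == b)
    f <- breedFreqs[snpIds, b]
    # genotype = number of B alleles per diploid
    nb <- matrix(rbinom(length(rows) * nS, 2L, rep(f, each = length(rows))),
                 nrow = length(rows))
    calls[rows, ] <- c("AA", "AB", "BB")[nb + 1L]
  }
  if (missingRate > 0)
    calls[matrix(runif(nSamp * nS) < missingRate, nSamp, nS)] <- NA
  calls[, failed] <- NA_character_
  new("GenotypeCallSet", calls = calls, breed = breed,
      assayStatus = ifelse(failed, "failed_design", "designed"),
      clusterOk = clusterOk)
}

#' Classify panel SNPs into the four performance classes
#'
#' The partition used to validate an array: `failed` (did not pass assay
#' design), `excluded` (could not be clustered into the three genotype
#' classes, or consisted of only heterozygotes — SNPs with no non-missing
#' call at all are also excluded), `monomorphic` (a single allele observed;
#' likely false positives of discovery), `polymorphic` (both alleles
#' observed in at least one breed).
#'
#' @param callset A [GenotypeCallSet-class].
#' @return Factor per SNP with levels `failed`, `excluded`, `monomorphic`,
#'   `polymorphic`.
#' @export
classifyPerformance <- function(callset) {
  nS <- ncol(callset@calls)
  out <- character(nS)
  for (j in seq_len(nS)) {
    if (callset@assayStatus[j] == "failed_design") {
      out[j] <- "failed"
      next
    }
    g <- callset@calls[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0 || !callset@clusterOk[j] || all(g == "AB")) {
      out[j] <- "excluded"
      next
    }
    # both alleles in at least one breed <=> any AB, or both homozygote
    # classes within one breed
    both <- FALSE
    for (b in unique(callset@breed)) {
      gb <- callset@calls[callset@breed == b, j]
      gb <- gb[!is.na(gb)]
      if (any(gb == "AB") || (any(gb == "AA") && any(gb == "BB"))) {
        both <- TRUE
        break
      }
    }
    out[j] <- if (both) "polymorphic" else "monomorphic"
  }
  factor(out, levels = c("failed", "excluded", "monomorphic", "polymorphic"))
}

#' Validation table with per-group percentages
#'
#' Tabulates performance classes per SNP group. Percentage conventions:
#' the failed percentage is over the full group; the excluded, monomorphic
#' and polymorphic percentages are over the SNPs that passed assay design
#' (`group total - failed`), consistent with how such validation tables
#' are printed. Percentages are rounded to one decimal; empty groups get
#' `NA` percentages.
#'
#' @param classes Factor from [classifyPerformance()].
#' @param groups Character vector of group labels, parallel to `classes`.
#' @return `data.frame`, one row per group plus columns
#'   `<class>_n` and `<class>_pct`.
#' @export
validationTable <- function(classes, groups) {
  tab <- table(groups, classes)
  counts <- as.data.frame.matrix(tab)
  validationTableFromCounts(
    data.frame(group = rownames(counts), failed = counts$failed,
               excluded = counts$excluded, monomorphic = counts$monomorphic,
               polymorphic = counts$polymorphic, stringsAsFactors = FALSE))
}

#' @rdname validationTable
#' @param counts `data.frame` with columns `group`, `failed`, `excluded`,
#'   `monomorphic`, `polymorphic` (counts).
#' @export
validationTableFromCounts <- function(counts) {
  total <- counts$failed + counts$excluded + counts$monomorphic +
    counts$polymorphic
  passed <- total - counts$failed
  pct <- function(x, denom) ifelse(denom > 0, round(100 * x / denom, 1),
                                   NA_real_)
  data.frame(group = counts$group,
             total_n = total,
             failed_n = counts$failed,
             failed_pct = pct(counts$failed, total),
             excluded_n = counts$excluded,
             excluded_pct = pct(counts$excluded, passed),
             monomorphic_n = counts$monomorphic,
             monomorphic_pct = pct(counts$monomorphic, passed),
             polymorphic_n = counts$polymorphic,
             polymorphic_pct = pct(counts$polymorphic, passed),
             stringsAsFactors = FALSE)
}
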