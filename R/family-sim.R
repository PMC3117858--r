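#' Full-sib mapping family design
#'
#' Defaults mirror a small commercial mapping population: two full-sib
#' families totalling 92 genotyped offspring.
#'
#' @param nFamilies Number of full-sib families (default 2).
#' @param offspringPerFamily Offspring per family (default 46, i.e. 92 in
#'   total over two families).
#' @param founderMaf Default founder minor-allele frequency used for markers
#'   whose table carries no `maf` column (default 0.5, maximally
#'   informative).
#' @return A list with class `FamilyDesign`.
#' @export
familyDesign <- function(nFamilies = 2, offspringPerFamily = 46,
                         founderMaf = 0.5) {
  stopifnot(nFamilies > 0, offspringPerFamily > 0,
            founderMaf > 0, founderMaf <= 0.5)
  structure(list(nFamilies = as.integer(nFamilies),
                 offspringPerFamily = as.integer(offspringPerFamily),
                 founderMaf = founderMaf),
            class = "FamilyDesign")
}

#' Simulate full-sib family genotypes over a genetic map
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions from the marker
#' allele frequency; meioses follow Mendelian transmission with crossovers
#' placed without interference (Haldane process): the recombination fraction
#' between adjacent markers `d` cM apart is `0.5 * (1 - exp(-0.02 d))`.
#' Markers on different chromosomes segregate independently. The Kosambi
#' function is used downstream only for reporting map distances.
#'
#' @param design A [familyDesign()].
#' @param markers `data.frame` with columns `marker`, `chrom`, `cm`
#'   (non-decreasing within chromosome) and optionally `maf` (founder
#'   frequency of allele B). Missing `cm` is an error.
#' @param genotypingErrorRate Probability that an offspring genotype is
#'   replaced by a uniformly random genotype (default 0).
#' @param seed Optional integer seed.
#' @param returnGametes If `TRUE`, attach per-parent transmitted-haplotype
#'   choice matrices (attribute `"gametes"`) for truth-level recombination
#'   accounting in tests.
#' @return A PED-like `data.frame`: columns `family`, `id`, `sire`, `dam`
#'   ("0" for founders), then one column per marker with genotypes
#'   `"AA"/"AB"/"BB"`.
#' @export
simulateFamilyGenotypes <- function(design, markers,
                                    genotypingErrorRate = 0,
                                    seed = NULL, returnGametes = FALSE) {
  stopifnot(inherits(design, "FamilyDesign"), is.data.frame(markers))
  if (!all(c("marker", "chrom", "cm") %in% names(markers)))
    stop("markers need columns marker, chrom, cm")
  if (anyNA(markers$cm)) stop("marker without map position")
  if (is.null(markers$maf)) markers$maf <- design$founderMaf
  markers <- markers[order(markers$chrom, markers$cm), , drop = FALSE]
  bad <- tapply(markers$cm, markers$chrom, function(x) any(diff(x) < 0))
  if (any(unlist(bad))) stop("cM positions must be non-decreasing")
  if (!is.null(seed)) set.seed(seed)

  M <- nrow(markers)
  chromOf <- markers$chrom
  # per-interval recombination fractions (0.5 across chromosome boundaries)
  r <- numeric(max(M - 1L, 0L))
  if (M > 1L) {
    d <- diff(markers$cm)
    sameChrom <- chromOf[-1] == chromOf[-M]
    r <- ifelse(sameChrom, 0.5 * (1 - exp(-0.02 * d)), 0.5)
  }

  drawHap <- function() as.integer(runif(M) < markers$maf)  # 1 = allele B
  gamete <- function(h1, h2) {
    # haplotype choice per marker: crossover between adjacent markers w.p. r
    choice <- integer(M)
    choice[1] <- sample(0:1, 1L)
    if (M > 1L) {
      sw <- runif(M - 1L) < r
      choice <- cumsum(c(choice[1], as.integer(sw))) %% 2L
    }
    list(allele = ifelse(choice == 0L, h1, h2), choice = choice)
  }
  code <- function(a, b) c("AA", "AB", "BB")[a + b + 1L]

  rows <- list()
  gametes <- list()
  for (f in seq_len(design$nFamilies)) {
    fam <- sprintf("F%d", f)
    sire <- list(h1 = drawHap(), h2 = drawHap())
    dam <- list(h1 = drawHap(), h2 = drawHap())
    sireId <- paste0(fam, "_S"); damId <- paste0(fam, "_D")
    rows[[length(rows) + 1L]] <- c(fam, sireId, "0", "0",
                                   code(sire$h1, sire$h2))
    rows[[length(rows) + 1L]] <- c(fam, damId, "0", "0",
                                   code(dam$h1, dam$h2))
    sireChoice <- matrix(NA_integer_, design$offspringPerFamily, M)
    damChoice <- matrix(NA_integer_, design$offspringPerFamily, M)
    for (o in seq_len(design$offspringPerFamily)) {
      gs <- gamete(sire$h1, sire$h2)
      gd <- gamete(dam$h1, dam$h2)
      sireChoice[o, ] <- gs$choice
      damChoice[o, ] <- gd$choice
      g <- code(gs$allele, gd$allele)
      if (genotypingErrorRate > 0) {
        err <- runif(M) < genotypingErrorRate
        if (any(err)) g[err] <- sample(c("AA", "AB", "BB"), sum(err),
                                       replace = TRUE)
      }
      rows[[length(rows) + 1L]] <- c(fam, sprintf("%s_O%03d", fam, o),
                                     sireId, damId, g)
    }
    gametes[[fam]] <- list(sire = sireChoice, dam = damChoice)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("family", "id", "sire", "dam", markers$marker)
  rownames(out) <- NULL
  attr(out, "markers") <- markers
  if (returnGametes) attr(out, "gametes") <- gametes
  out
}

#' Write / read a PED-like genotype table
#'
#' @param ped A `data.frame` from [simulateFamilyGenotypes()].
#' @param file TSV path.
#' @return `readPedTable()` returns the `data.frame` (missing genotypes as
#'   `NA`).
#' @export
writePedTable <- function(ped, file) {
  write.table(ped, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePedTable
#' @export
readPedTable <- function(file) {
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", "--", "0/0"))
}
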