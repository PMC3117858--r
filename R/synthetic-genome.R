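#' Default chromosome configuration for a desk-scale synthetic genome
#'
#' A 240 kb miniature of avian genome architecture: one macro-chromosome,
#' one intermediate chromosome and two micro-chromosomes. Used as the
#' default input of [generateGenome()].
#'
#' @return `data.frame` with columns `name`, `size`, `class`.
#' @export
defaultGenomeConfig <- function() {
  data.frame(
    name  = c("chr1", "chr2", "chr3", "chr4"),
    size  = c(150000L, 50000L, 20000L, 20000L),
    class = c("macro", "intermediate", "micro", "micro"),
    stringsAsFactors = FALSE
  )
}

#' Generate a random synthetic genome
#'
#' Draws i.i.d. sequence per chromosome with a per-size-class GC fraction.
#' Micro-chromosomes default to a higher GC content than macro-chromosomes,
#' reflecting the elevated GC of avian micro-chromosomes.
#'
#' @param chromosomes `data.frame` with columns `name`, `size` (bp, > 0) and
#'   `class` (see [SyntheticGenome-class]). Default: [defaultGenomeConfig()].
#' @param gcBias Named numeric, GC fraction per size class.
#' @param seed Optional integer; fixing it makes the output byte-identical
#'   across runs.
#' @return A [SyntheticGenome-class].
#' @examples
#' g <- generateGenome(seed = 1)
#' totalBp(g)
#' @export
generateGenome <- function(chromosomes = defaultGenomeConfig(),
                           gcBias = c(macro = 0.41, intermediate = 0.45,
                                      micro = 0.52, unplaced_contig = 0.52,
                                      mito = 0.45),
                           seed = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "size", "class") %in% names(chromosomes)))
  if (any(chromosomes$size <= 0))
    stop("chromosome sizes must be strictly positive")
  gc <- gcBias[chromosomes$class]
  if (anyNA(gc))
    stop("no GC bias configured for class(es): ",
         paste(setdiff(chromosomes$class, names(gcBias)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(nrow(chromosomes)),
                 function(i) .randomDna(chromosomes$size[i], gc[[i]]), "")
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- chromosomes$name
  SyntheticGenome(dss, chromosomes$class)
}

#' Write / read a genome as FASTA
#'
#' @param genome A [SyntheticGenome-class] or `DNAStringSet`.
#' @param file Path to a FASTA file.
#' @return `readGenomeFasta()` returns a `DNAStringSet` (size classes are not
#'   stored in FASTA).
#' @export
writeGenomeFasta <- function(genome, file) {
  seqs <- if (is(genome, "SyntheticGenome")) genomeSequences(genome) else genome
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(file) Biostrings::readDNAStringSet(file)

#' Plant biallelic SNPs with known per-population frequencies
#'
#' Positions are drawn per chromosome as a Poisson number of sites placed
#' uniformly without replacement (so no two SNPs share a position). The
#' reference allele is the genome base; the alternative allele is drawn
#' uniformly from the other three bases. Each SNP receives a minor-allele
#' frequency from a flat spectrum (default uniform on \[0.1, 0.5\], mean 0.30,
#' emulating the flat high-MAF spectrum targeted by pooled RRL discovery),
#' and each population's alternative-allele frequency is either the shared
#' draw (with probability `share`) or an independent redraw, with the
#' minor/major orientation randomized per population.
#'
#' @param genome A [SyntheticGenome-class].
#' @param density Expected SNPs per bp (default 1/500, a realistic
#'   between-line density for commercial chicken).
#' @param mafSpectrum Numeric length 2: bounds of the uniform minor-allele
#'   frequency spectrum, within (0, 0.5].
#' @param populations Character vector of population ids.
#' @param share Probability that a population re-uses the shared frequency
#'   draw instead of an independent one.
#' @param seed Optional integer seed.
#' @return A [GenomicRanges::GRanges] (width-1 positions) with metadata
#'   columns `ref`, `alt` and one `freq_<population>` column per population
#'   holding the alternative-allele frequency. Names are `chrom:pos` keys.
#' @export
plantSnps <- function(genome, density = 1 / 500, mafSpectrum = c(0.1, 0.5),
                      populations = c("B1", "B2", "BL", "WL"),
                      share = 0.5, seed = NULL) {
  stopifnot(is(genome, "SyntheticGenome"), density >= 0)
  if (length(mafSpectrum) != 2 || mafSpectrum[1] <= 0 ||
      mafSpectrum[2] > 0.5 || mafSpectrum[1] > mafSpectrum[2])
    stop("mafSpectrum must be bounds within (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  seqs <- genomeSequences(genome)
  chromStr <- as.character(seqs)
  out <- list()
  for (chr in names(seqs)) {
    L <- nchar(chromStr[[chr]])
    n <- if (density == 0) 0L else rpois(1L, L * density)
    if (n > L / 2)
      stop("SNP density too high: positions collide irresolvably on ", chr)
    if (n == 0L) next
    pos <- sort(sample.int(L, n))
    ref <- substring(chromStr[[chr]], pos, pos)
    keep <- ref %in% c("A", "C", "G", "T")
    pos <- pos[keep]; ref <- ref[keep]
    if (length(pos) == 0L) next
    out[[chr]] <- data.frame(chrom = chr, pos = pos, ref = ref,
                             stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character())
  nsnp <- nrow(df)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$pos, width = 1),
    seqlengths = stats::setNames(Biostrings::width(seqs), names(seqs)))
  if (nsnp > 0) {
    gr$ref <- df$ref
    gr$alt <- .otherBase(df$ref)
    m <- runif(nsnp, mafSpectrum[1], mafSpectrum[2])
    for (p in populations) {
      use_shared <- runif(nsnp) < share
      mp <- ifelse(use_shared, m, runif(nsnp, mafSpectrum[1], mafSpectrum[2]))
      flip <- runif(nsnp) < 0.5
      S4Vectors::mcols(gr)[[paste0("freq_", p)]] <- ifelse(flip, 1 - mp, mp)
    }
    names(gr) <- paste0(df$chrom, ":", df$pos)
  } else {
    gr$ref <- character(0)
    gr$alt <- character(0)
    for (p in populations)
      S4Vectors::mcols(gr)[[paste0("freq_", p)]] <- numeric(0)
  }
  S4Vectors::metadata(gr)$populations <- populations
  gr
}

#' Serialize / load a truth-SNP table as TSV
#'
#' @param snps GRanges from [plantSnps()].
#' @param file TSV path.
#' @return `readTruthSnps()` returns a `data.frame` with columns `chrom`,
#'   `pos`, `ref`, `alt` and the `freq_*` columns.
#' @export
writeTruthSnps <- function(snps, file) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(snps)),
                   pos = GenomicRanges::start(snps),
                   as.data.frame(S4Vectors::mcols(snps)),
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTruthSnps
#' @export
readTruthSnps <- function(file) {
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Assign assay design scores
#'
#' Stand-in for an array vendor's assay design tool: draws a score in
#' \[0, 1\] per SNP from a configurable distribution. Only the threshold
#' behaviour (score >= 0.6 eligible) matters downstream. The default Beta
#' shape puts roughly two thirds of SNPs above 0.6, matching the pass rate
#' observed for real design-score screens.
#'
#' @param snps A GRanges (named) or a character vector of SNP ids.
#' @param spec Distribution spec: `list(type = "beta", shape1, shape2)`,
#'   `list(type = "uniform", min, max)` or `list(type = "constant", value)`.
#' @param seed Optional integer seed; fixed seed gives identical scores.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
assignDesignScores <- function(snps,
                               spec = list(type = "beta", shape1 = 3,
                                           shape2 = 1.3),
                               seed = NULL) {
  ids <- if (is.character(snps)) snps else names(snps)
  if (is.null(ids)) stop("snps must be named or a character vector of ids")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ids)
  s <- switch(spec$type,
    constant = rep(spec$value, n),
    uniform = runif(n, spec$min %||% 0, spec$max %||% 1),
    beta = rbeta(n, spec$shape1, spec$shape2),
    stop("unknown design-score spec type: ", spec$type))
  if (any(s < 0 | s > 1)) stop("design scores must lie in [0, 1]")
  stats::setNames(s, ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
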