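# Small in-code fixtures shared by the tests.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# fixed-width reads with uniform (or per-read) Phred qualities
mkReads <- function(seqs, quals = 35, names = NULL) {
  L <- nchar(seqs)
  qs <- strrep(intToUtf8(33L + rep_len(as.integer(quals), length(seqs)),
                         multiple = TRUE), L)
  x <- QualityScaledDNAStringSet(DNAStringSet(seqs), PhredQuality(qs))
  names(x) <- if (is.null(names)) sprintf("r%03d", seq_along(seqs)) else names
  x
}

# one-chromosome genome from a literal sequence
mkGenome <- function(seq, name = "chrT", class = "micro") {
  dss <- DNAStringSet(setNames(seq, name))
  SyntheticGenome(dss, class)
}

# alignment table row(s) in the mapReads() output shape
mkAln <- function(chrom, pos, seq, qual = NULL, mapq = 37, strand = "+",
                  qname = NULL) {
  n <- length(pos)
  data.frame(
    qname = if (is.null(qname)) sprintf("a%04d", seq_len(n)) else qname,
    status = "unique", chrom = chrom, pos = as.integer(pos),
    strand = rep_len(strand, n), mapq = rep_len(as.integer(mapq), n),
    mismatches = 0L, seq = seq,
    qual = if (is.null(qual)) strrep("D", nchar(seq)) else qual,
    stringsAsFactors = FALSE)
}

# full-sib family genotypes built directly from transmitted sire alleles:
# dam is AA at both markers, sire AB/AB in coupling phase; `recomb` of the
# `n` meioses are recombinant. Offspring genotypes then reveal the sire
# gamete exactly.
mkTwoMarkerFamily <- function(recomb, n) {
  stopifnot(recomb <= n)
  s1 <- c(rep("A", n - recomb), rep("B", recomb))   # marker 1 transmission
  s2 <- c(rep("A", n - recomb), rep("A", recomb))   # marker 2: parental = A
  g1 <- ifelse(s1 == "A", "AA", "AB")
  g2 <- ifelse(s2 == "A", "AA", "AB")
  # recombinants carry (B, A) gametes: marker1 B, marker2 A
  g1[seq_len(n) > n - recomb] <- "AB"
  data.frame(
    family = "F1",
    id = c("S", "D", sprintf("O%03d", seq_len(n))),
    sire = c("0", "0", rep("S", n)),
    dam = c("0", "0", rep("D", n)),
    m1 = c("AB", "AA", g1),
    m2 = c("AB", "AA", g2),
    stringsAsFactors = FALSE)
}

# closed-form two-point LOD oracle on phase-known counts
lodOracle <- function(R, N) {
  th <- R / N
  if (th >= 0.5) return(0)
  if (R == 0) return(N * log10(2))
  R * log10(th) + (N - R) * log10(1 - th) + N * log10(2)
}

# the standard two-hidden-micro-chromosome marker map
hiddenChromMarkers <- function(spacingCm = 1.5) {
  data.frame(
    marker = c(sprintf("u1_%02d", 1:15), sprintf("u2_%02d", 1:13)),
    chrom = rep(c("new1", "new2"), c(15, 13)),
    cm = c((0:14) * spacingCm, (0:12) * spacingCm),
    stringsAsFactors = FALSE)
}
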