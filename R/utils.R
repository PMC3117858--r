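# Internal helpers shared across modules.

# i.i.d. random DNA with a given GC fraction
.randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Phred integer -> Sanger-encoded quality string of length len
.phredString <- function(q, len) {
  strrep(intToUtf8(33L + as.integer(q), multiple = TRUE), len)
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# fixed-width character vector -> matrix of single characters (rows = strings)
.charMatrix <- function(x, width) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

# inverse of .charMatrix
.collapseRows <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# substitute a different base, uniformly over the other three
.otherBase <- function(b) {
  bases <- c("A", "C", "G", "T")
  vapply(b, function(x) sample(setdiff(bases, x), 1L), "", USE.NAMES = FALSE)
}

.isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# seed helper: derive a distinct 31-bit sub-seed from a base seed
.subSeed <- function(seed, k) {
  (as.integer(seed) * 67L + as.integer(k) * 9973L) %% 2147483629L
}
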