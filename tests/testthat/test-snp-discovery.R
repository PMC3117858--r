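test_that("augmented reference keeps contigs at the length threshold", {
  assembly <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  contigs <- Biostrings::DNAStringSet(c(c150 = strrep("AC", 75),
                                        c250 = strrep("AG", 125),
                                        c200 = strrep("GT", 100)))
  ref <- buildAugmentedReference(assembly, contigs, minContigBp = 200,
                                 spacerLen = 50)
  expect_setequal(ref@offsets$contig, c("c250", "c200"))
  art <- genomeSequences(ref)[[ref@artificialName]]
  expect_equal(length(art), 250L + 50L + 200L)

  # coordinate round trip over every kept contig base
  for (ct in ref@offsets$contig) {
    w <- ref@offsets$width[ref@offsets$contig == ct]
    ap <- contigToArtificial(ref, rep(ct, w), seq_len(w))
    back <- artificialToContig(ref, ap)
    expect_identical(back$contig, rep(ct, w))
    expect_identical(back$pos, seq_len(w))
  }
  # spacer positions map to no contig
  sp <- artificialToContig(ref, 251:300)
  expect_true(all(is.na(sp$contig)))

  # empty contig set: artificial chromosome absent
  ref0 <- buildAugmentedReference(assembly, contigs[0])
  expect_equal(length(genomeSequences(ref0)), 1L)

  expect_error(buildAugmentedReference(assembly,
    Biostrings::DNAStringSet(setNames(c(strrep("A", 300), strrep("C", 300)),
                                      c("dup", "dup")))),
    "duplicate contig id")
})

test_that("mapReads distinguishes unique, multi and 1-mismatch placements", {
  set.seed(91)
  core <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  dupBlock <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  s <- paste0(core, dupBlock, core2 <- paste(
    sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), dupBlock)
  g <- Biostrings::DNAStringSet(c(chr = s))

  exact <- substring(s, 101, 136)
  fromDup <- substring(s, 501 + 10, 501 + 45)  # inside the duplicated block
  mm1 <- exact
  substr(mm1, 18, 18) <- setdiff(c("A", "C", "G", "T"),
                                 substring(mm1, 18, 18))[1]
  aln <- mapReads(mkReads(c(exact, fromDup, mm1)), g)
  expect_equal(aln$status, c("unique", "multi", "unique"))
  expect_equal(aln$pos[1], 101L)
  expect_equal(aln$mapq[c(1, 3)], c(37L, 25L))
  expect_equal(aln$pos[3], 101L)
  # reverse-strand read is reported reference-oriented
  rcRead <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(exact)))
  alnR <- mapReads(mkReads(rcRead), g)
  expect_equal(alnR$strand, "-")
  expect_equal(alnR$pos, 101L)
  expect_equal(alnR$seq, exact)
})

test_that("error-free simulated reads map back to their origin", {
  g <- generateGenome(seed = 101)
  chromStr <- as.character(genomeSequences(g))
  set.seed(102)
  n <- 10000
  chr <- sample(names(chromStr), n, replace = TRUE,
                prob = nchar(chromStr) / sum(nchar(chromStr)))
  pos <- vapply(chr, function(c) sample.int(nchar(chromStr[[c]]) - 35, 1L),
                1L)
  reads <- substring(chromStr[chr], pos, pos + 35)
  aln <- mapReads(mkReads(reads), g)
  okUnique <- aln$status == "unique"
  expect_gte(mean(okUnique), 0.99)
  hitOrigin <- okUnique & aln$chrom == chr & aln$pos == pos
  expect_gte(mean(hitOrigin), 0.99)
})

test_that("SAM emission round-trips through Rsamtools", {
  g <- generateGenome(seed = 111)
  chromStr <- as.character(genomeSequences(g))
  reads <- substring(chromStr[["chr1"]], c(101, 2001, 40001),
                     c(136, 2036, 40036))
  aln <- mapReads(mkReads(reads), g)
  f <- tempfile(fileext = ".sam")
  writeSamAlignments(aln, setNames(Biostrings::width(genomeSequences(g)),
                                   names(genomeSequences(g))), f)
  back <- readSamAlignments(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$mapq, aln$mapq)
  expect_equal(back$seq, aln$seq)
})

test_that("callSnps enforces the pooled calling thresholds", {
  g <- mkGenome(strrep("ACGT", 250))  # chrT, 1000 bp, ref at 101 is A
  mkPile <- function(pos, nRef, nAlt, alt = "C", mapq = 37) {
    refBase <- substring(strrep("ACGT", 250), pos, pos)
    reads <- c(rep(refBase, nRef), rep(alt, nAlt))
    # single-base alignments are inconvenient; build 36-mers differing at pos
    tmpl <- substring(strrep("ACGT", 250), pos - 10, pos + 25)
    seqs <- vapply(reads, function(b) {
      s <- tmpl; substr(s, 11, 11) <- b; s
    }, "")
    mkAln("chrT", rep(pos - 10L, length(seqs)), seqs, mapq = mapq)
  }
  # 10 ref / 2 alt: minor below three reads -> no call
  out <- callSnps(mkPile(101, 10, 2), g, meanDepth = 20)
  expect_equal(nrow(out$calls), 0L)
  # 9 ref / 3 alt at depth 12 <= 4 x 20 -> called with maf 0.25
  out2 <- callSnps(mkPile(101, 9, 3), g, meanDepth = 20)
  expect_equal(nrow(out2$calls), 1L)
  expect_equal(out2$calls$maf, 0.25)
  expect_equal(out2$calls$ref, "A")
  expect_gte(out2$calls$consensus_quality, 10)
  # depth 100 with mean depth 20 -> depth cap rejects
  out3 <- callSnps(mkPile(101, 60, 40), g, meanDepth = 20)
  expect_equal(nrow(out3$calls), 0L)
  expect_equal(unname(out3$rejects["depth_cap"]), 1L)
  # low map quality reads are excluded from the counts entirely
  out4 <- callSnps(mkPile(101, 9, 3, mapq = 5), g, meanDepth = 20)
  expect_equal(nrow(out4$calls), 0L)
})

test_that("estimateMaf counts reads and stays below 0.5", {
  expect_equal(estimateMaf(5, 5), 0.5)
  expect_equal(estimateMaf(9, 3), 0.25)
  expect_equal(estimateMaf(12, 0), 0)
  expect_error(estimateMaf(0, 0), "zero")
})

test_that("mergePopulations combines calls, known flags and conflicts", {
  callRow <- function(pop, chrom, pos, ref, alt, nr, na) {
    data.frame(population = pop, chrom = chrom, pos = pos, ref = ref,
               alt = alt, ref_count = nr, alt_count = na,
               maf = estimateMaf(nr, na), consensus_quality = 60,
               best_mapq = 37, stringsAsFactors = FALSE)
  }
  calls <- list(
    B1 = rbind(callRow("B1", "chr1", 100, "A", "G", 20, 10),
               callRow("B1", "chr1", 500, "C", "T", 15, 5)),
    BL = rbind(callRow("BL", "chr1", 100, "A", "G", 12, 18),
               callRow("BL", "chr1", 900, "C", "T", 9, 3),
               callRow("BL", "chr1", 500, "C", "A", 8, 8)))  # conflict
  known <- data.frame(chrom = "chr1", pos = 900)
  out <- mergePopulations(calls, known)
  m <- out$merged
  expect_equal(nrow(m), 3L)
  site100 <- m[m$pos == 100, ]
  expect_equal(site100$n_populations_detected, 2L)
  # count-weighted overall MAF: pooled 32 ref / 28 alt
  expect_equal(site100$overall_maf, 28 / 60)
  expect_true(m$known_flag[m$pos == 900])
  expect_true(m$conflict[m$pos == 500])
  expect_equal(out$summary$n_total, 2L)  # conflict excluded
  expect_equal(out$summary$n_in_ge2_pops, 1L)
  expect_equal(out$summary$n_known, 1L)
})

test_that("VCF emission round-trips through VariantAnnotation", {
  library(VariantAnnotation)
  calls <- data.frame(population = "B1", chrom = c("chr1", "chr2"),
                      pos = c(100L, 250L), ref = c("A", "C"),
                      alt = c("G", "T"), ref_count = c(20L, 9L),
                      alt_count = c(10L, 3L), maf = c(1 / 3, 0.25),
                      consensus_quality = c(60, 42.5),
                      best_mapq = c(37L, 37L), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  writeSnpVcf(calls, f)
  v <- suppressWarnings(readVcf(f))
  expect_equal(as.integer(start(rowRanges(v))), calls$pos)
  expect_equal(info(v)$RO, calls$ref_count)
  expect_equal(info(v)$AO, calls$alt_count)
  expect_equal(info(v)$MAF, calls$maf, tolerance = 1e-5)
})

test_that("the discovery pipeline recovers a planted SNP end to end", {
  g <- generateGenome(data.frame(name = "mini", size = 30000L,
                                 class = "micro"), seed = 121)
  snps <- plantSnps(g, density = 1 / 800, populations = "P", seed = 122)
  inv <- digestGenome(g)
  pr <- simulatePoolReads(g, snps, inv, sizeWindow(125, 200),
                          poolSpec("P", 25, 40), errorRate = 0, seed = 123)
  qc <- runReadQc(c(pr$mate1, pr$mate2))
  aln <- uniqueAlignments(mapReads(qc$reads, g))
  out <- callSnps(aln, g, populationId = "P")
  key <- paste0(out$calls$chrom, ":", out$calls$pos)
  expect_gt(nrow(out$calls), 0)
  expect_true(all(key %in% names(snps)))  # no false positives
})
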