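test_that("Infinium typing: exactly four of the six pairs are type II", {
  pairs <- t(combn(c("A", "C", "G", "T"), 2))
  types <- classifyInfinium(pairs[, 1], pairs[, 2])
  expect_equal(sum(types == "II"), 4L)
  expect_equal(classifyInfinium("A", "G"), "II")
  expect_equal(classifyInfinium("G", "A"), "II")
  expect_equal(classifyInfinium("A", "T"), "I")
  expect_equal(classifyInfinium("G", "C"), "I")
  expect_error(classifyInfinium("A", "A"), "distinct")
})

test_that("neighbour flag uses a strict 10 bp window", {
  cands <- data.frame(id = c("a", "b", "c", "d"),
                      chrom = c("c1", "c1", "c1", "c2"),
                      pos = c(100L, 105L, 300L, 100L))
  allv <- data.frame(chrom = c("c1", "c1", "c1", "c2", "c1"),
                     pos = c(100L, 105L, 300L, 100L, 311L))
  fl <- flagNeighbors(cands, allv, windowBp = 10)
  # 100 and 105 flag each other; 300 has 311 at distance 11 -> clear;
  # c2:100 is alone on its chromosome
  expect_equal(fl, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the default priority lattice is a 25-class partition", {
  # one candidate per lattice cell
  mafFor <- function(tier) c(0.35, 0.25, 0.15, 0.07, 0.01)[tier]
  rows <- list()
  for (lvl in 1:5) for (tier in 1:5) {
    maf <- mafFor(tier)
    noMaf <- tier == 5 && lvl %in% c(1, 5)  # absent-MAF route to tier 5
    rows[[length(rows) + 1L]] <- data.frame(
      validated = lvl == 1,
      source = c("known_db", "rrl_and_db", "rrl_novel", "rrl_novel",
                 "known_db")[lvl],
      maf_broiler = if (noMaf) NA_real_ else maf,
      maf_layer = if (noMaf || lvl == 4) NA_real_ else maf,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  cls <- assignPriority(grid)
  expect_equal(sort(cls), 1:25)

  # the stated anchor classes
  expect_equal(assignPriority(data.frame(validated = TRUE,
    source = "known_db", maf_broiler = 0.32, maf_layer = 0.41)), 1L)
  expect_equal(assignPriority(data.frame(validated = FALSE,
    source = "known_db", maf_broiler = NA_real_, maf_layer = NA_real_)),
    25L)
  # ineligible candidates are an error, not a class
  expect_error(assignPriority(data.frame(validated = TRUE,
    source = "known_db", maf_broiler = 0.3, maf_layer = 0.3,
    infinium_type = "I")), "ineligible")
  expect_error(assignPriority(data.frame(validated = TRUE,
    source = "known_db", maf_broiler = 0.3, maf_layer = 0.3,
    design_score = 0.5)), "ineligible")
  expect_error(assignPriority(data.frame(validated = TRUE,
    source = "known_db", maf_broiler = 0.3, maf_layer = 0.3,
    neighbor_excluded = TRUE)), "ineligible")
})

test_that("spacing plan anchors macro and micro and interpolates between", {
  tab <- data.frame(name = c("c1", "c2", "c3"),
                    length = c(150000L, 50000L, 20000L),
                    class = c("macro", "intermediate", "micro"))
  plan <- spacingPlan(tab)
  expect_equal(plan$spacing[plan$class == "macro"], 20000)
  expect_equal(plan$spacing[plan$class == "micro"], 4000)
  mid <- plan$spacing[plan$class == "intermediate"]
  expect_gt(mid, 4000); expect_lt(mid, 20000)
  expect_true(all(diff(plan$spacing) <= 0))
  expect_error(spacingPlan(data.frame(name = "x", length = 1L,
                                      class = "mystery")), "unknown")
})

test_that("selectPanel replays the greedy scroll rule", {
  cands <- data.frame(id = paste0("s", 1:5), chrom = "c1",
                      pos = c(5000L, 18000L, 22000L, 39000L, 41000L),
                      class = c(3L, 1L, 2L, 1L, 5L),
                      maf_broiler = 0.3, maf_layer = 0.3)
  plan <- data.frame(name = "c1", length = 100000L, class = "macro",
                     spacing = 20000)
  sel <- selectPanel(cands, plan)
  expect_equal(sel$pos, c(18000L, 39000L))
  gaps <- attr(sel, "gaps")
  expect_gt(nrow(gaps), 0)  # the walk continues past 39 kb finding nothing

  # empty candidate set
  sel0 <- selectPanel(cands[0, ], plan)
  expect_equal(nrow(sel0), 0L)

  # uniform rescaling of class numbers leaves the selection unchanged
  c2 <- cands; c2$class <- c2$class * 2L
  expect_equal(selectPanel(c2, plan)$pos, sel$pos)

  # determinism
  expect_identical(selectPanel(cands, plan)$id, sel$id)
})

test_that("improving a candidate's class never removes it from the panel", {
  set.seed(33)
  cands <- data.frame(id = sprintf("s%03d", 1:120), chrom = "c1",
                      pos = sort(sample.int(200000L, 120)),
                      class = sample(1:25, 120, TRUE),
                      maf_broiler = runif(120, 0, 0.5),
                      maf_layer = runif(120, 0, 0.5))
  plan <- data.frame(name = "c1", length = 200000L, class = "macro",
                     spacing = 20000)
  base <- selectPanel(cands, plan)
  for (pick in sample(which(cands$id %in% base$id), 5)) {
    mod <- cands
    mod$class[pick] <- 1L
    expect_true(cands$id[pick] %in% selectPanel(mod, plan)$id)
  }
})

test_that("median realized spacing tracks the plan on dense candidates", {
  set.seed(44)
  cands <- data.frame(id = sprintf("s%05d", 1:4000), chrom = "c1",
                      pos = sort(sample.int(1000000L, 4000)),
                      class = sample(1:25, 4000, TRUE),
                      maf_broiler = runif(4000, 0, 0.5),
                      maf_layer = runif(4000, 0, 0.5))
  plan <- data.frame(name = "c1", length = 1000000L, class = "macro",
                     spacing = 20000)
  sel <- selectPanel(cands, plan)
  medGap <- median(diff(sort(sel$pos)))
  expect_lt(abs(medGap - 20000) / 20000, 0.25)
})

test_that("assembleManifest sums categories and rejects duplicate ids", {
  chromSel <- data.frame(id = paste0("c", 1:10), chrom = "c1",
                         pos = (1:10) * 1000L)
  addons <- list(
    unplaced_contig = data.frame(id = paste0("u", 1:4),
                                 chrom = "chrArtificial",
                                 pos = (1:4) * 500L),
    chr_random = data.frame(id = paste0("r", 1:3), chrom = "chr1_random",
                            pos = (1:3) * 100L),
    mito = data.frame(id = "m1", chrom = "chrM", pos = 5L))
  man <- assembleManifest(chromSel, addons)
  cc <- categoryCounts(man)
  expect_equal(unname(cc), c(10L, 4L, 3L, 1L))
  expect_equal(sum(cc), nrow(manifestSnps(man)))

  expect_equal(sum(categoryCounts(assembleManifest(chromSel))), 10L)

  bad <- addons
  bad$mito$id <- "c1"
  expect_error(assembleManifest(chromSel, bad), "duplicate id")
})

test_that("spacing distribution counts within-chromosome gaps only", {
  chromSel <- data.frame(
    id = paste0("s", 1:5),
    chrom = c("c1", "c1", "c2", "c3", "c3"),
    pos = c(1000L, 21000L, 7000L, 2000L, 6000L))
  man <- assembleManifest(chromSel)
  out <- spacingDistribution(man, c(c1 = "macro", c2 = "micro",
                                    c3 = "micro"))
  expect_equal(nrow(out$gaps), 2L)  # c2 contributes none
  expect_equal(sort(out$gaps$gap), c(4000L, 20000L))
  expect_equal(sum(out$histogram), 2L)
})

test_that("buildCandidateTable bridges merged calls to panel candidates", {
  merged <- data.frame(
    chrom = "chr1", pos = c(100L, 108L, 5000L), ref = c("A", "C", "G"),
    alt = c("G", "G", "T"), n_populations_detected = c(2L, 1L, 2L),
    conflict = c(FALSE, FALSE, FALSE),
    known_flag = c(TRUE, FALSE, FALSE),
    overall_maf = c(0.3, 0.2, 0.4),
    maf_B1 = c(0.30, NA, 0.45), maf_B2 = c(0.32, NA, 0.35),
    maf_BL = c(0.28, 0.2, NA), maf_WL = c(0.30, 0.2, NA),
    stringsAsFactors = FALSE)
  scores <- setNames(c(0.9, 0.7, 0.65),
                     c("chr1:100", "chr1:108", "chr1:5000"))
  cand <- buildCandidateTable(merged, scores,
                              validatedIds = "chr1:100")
  expect_equal(cand$infinium_type, c("II", "I", "II"))
  expect_equal(cand$source, c("rrl_and_db", "rrl_novel", "rrl_novel"))
  expect_true(cand$validated[1])
  expect_equal(cand$maf_broiler, c(0.31, NA, 0.4))
  expect_equal(cand$maf_layer, c(0.29, 0.2, NA))
  # 100 and 108 are within 10 bp of each other; 5000 is clear
  expect_equal(cand$neighbor_excluded, c(TRUE, TRUE, FALSE))
  # eligibility composes type, score and neighbour flags
  elig <- eligibleCandidates(cand)
  expect_equal(elig$id, "chr1:5000")
})
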