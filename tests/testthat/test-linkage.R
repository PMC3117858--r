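test_that("mendelianCheck flags impossible transmissions and cleans them", {
  ped <- data.frame(
    family = "F1",
    id = c("S", "D", "O1", "O2", "O3"),
    sire = c("0", "0", "S", "S", "S"),
    dam = c("0", "0", "D", "D", "D"),
    m1 = c("AA", "AA", "AB", "AA", "AA"),   # O1 impossible (AA x AA -> AB)
    m2 = c("AA", "BB", "AB", "AB", "AB"),   # all fine
    m3 = c("AA", NA, "BB", "AA", "AB"),     # O1 impossible (AA x ? -> BB)
    stringsAsFactors = FALSE)
  out <- mendelianCheck(ped)
  expect_equal(nrow(out$errors), 2L)
  expect_setequal(out$errors$marker, c("m1", "m3"))
  expect_true(all(out$errors$id == "O1"))
  expect_true(is.na(out$ped$m1[out$ped$id == "O1"]))
  expect_true(is.na(out$ped$m3[out$ped$id == "O1"]))
  # untouched genotypes survive
  expect_equal(out$ped$m2, ped$m2)
})

test_that("two-point LOD matches the closed-form binomial likelihood ratio", {
  # phase-known construction: counts are exact, so the statistic must equal
  # the closed form over a grid of (R, N)
  for (N in c(10, 20, 50)) {
    for (R in 0:4) {
      if (R / N >= 0.5) next
      tp <- twopoint("m1", "m2", mkTwoMarkerFamily(R, N))
      expect_equal(tp$theta, R / N, tolerance = 1e-12)
      expect_equal(tp$lod, lodOracle(R, N), tolerance = 1e-9)
      expect_equal(tp$n_informative, N)
    }
  }
  # spec anchor values
  expect_equal(twopoint("m1", "m2", mkTwoMarkerFamily(0, 20))$lod,
               6.0206, tolerance = 1e-3)
  expect_equal(twopoint("m1", "m2", mkTwoMarkerFamily(2, 20))$lod,
               3.19697, tolerance = 1e-3)
  # theta 0.5 -> lod exactly 0
  expect_equal(twopoint("m1", "m2", mkTwoMarkerFamily(10, 20))$lod, 0)
  # no informative meioses -> absent, distinguishable from lod 0
  pedU <- mkTwoMarkerFamily(0, 5)
  pedU$m1 <- "AA"
  expect_null(twopoint("m1", "m2", pedU))
})

test_that("recombination fractions converge to map-implied values", {
  # theta = 0.1 corresponds to Haldane distance -50 log(1 - 0.2)
  d <- -50 * log(1 - 0.2)
  mk <- data.frame(marker = c("a", "b"), chrom = "c1", cm = c(0, d))
  ped <- simulateFamilyGenotypes(familyDesign(1, 5000), mk, seed = 14,
                                 returnGametes = TRUE)
  gam <- attr(ped, "gametes")$F1
  recFrac <- function(ch) mean(ch[, 1] != ch[, 2])
  obs <- mean(c(recFrac(gam$sire), recFrac(gam$dam)))  # 10,000 meioses
  expect_gte(obs, 0.09); expect_lte(obs, 0.11)

  # zero map distance: no recombinant meioses
  mk0 <- data.frame(marker = c("a", "b"), chrom = "c1", cm = c(5, 5))
  ped0 <- simulateFamilyGenotypes(familyDesign(1, 500), mk0, seed = 15,
                                  returnGametes = TRUE)
  g0 <- attr(ped0, "gametes")$F1
  expect_equal(recFrac(g0$sire), 0)
  expect_equal(recFrac(g0$dam), 0)

  # unlinked chromosomes: independent segregation
  mkU <- data.frame(marker = c("a", "b"), chrom = c("c1", "c2"),
                    cm = c(0, 0))
  pedU <- simulateFamilyGenotypes(familyDesign(1, 5000), mkU, seed = 16,
                                  returnGametes = TRUE)
  gU <- attr(pedU, "gametes")$F1
  obsU <- mean(c(recFrac(gU$sire), recFrac(gU$dam)))
  expect_lt(abs(obsU - 0.5), 0.013)

  expect_error(simulateFamilyGenotypes(familyDesign(),
    data.frame(marker = "a", chrom = "c1", cm = NA)), "map position")
})

test_that("simulated families are Mendelian-consistent without errors", {
  mk <- hiddenChromMarkers()
  ped <- simulateFamilyGenotypes(familyDesign(), mk, seed = 17)
  expect_equal(nrow(mendelianCheck(ped)$errors), 0L)
  withErr <- simulateFamilyGenotypes(familyDesign(), mk,
                                     genotypingErrorRate = 0.05, seed = 18)
  expect_gt(nrow(mendelianCheck(withErr)$errors), 0L)
})

test_that("chromosome assignment needs multiple unconflicted supporters", {
  res <- data.frame(
    marker_a = rep("u", 6),
    marker_b = c("a1", "a2", "a3", "b1", "b2", "c1"),
    theta = 0.05,
    lod = c(7, 7, 7, 1, 1, 1),
    n_informative = 40)
  idx <- data.frame(marker = c("a1", "a2", "a3", "b1", "b2", "c1"),
                    chrom = c("chr5", "chr5", "chr5", "chr2", "chr2",
                              "chr3"))
  out <- assignToChromosome(res, idx)
  expect_equal(out$chrom, "chr5")
  expect_false(out$conflict)

  # a single supporter is not enough
  res1 <- res; res1$lod <- c(7, 1, 1, 1, 1, 1)
  expect_true(is.na(assignToChromosome(res1, idx)$chrom))

  # two qualifying chromosomes -> unassigned with conflict
  res2 <- res; res2$lod <- c(7, 7, 1, 7, 7, 1)
  out2 <- assignToChromosome(res2, idx)
  expect_true(is.na(out2$chrom))
  expect_true(out2$conflict)
})

test_that("new groups are LOD>4 components, never singletons", {
  mkRes <- function(a, b, lod) data.frame(marker_a = a, marker_b = b,
                                          theta = 0.05, lod = lod,
                                          n_informative = 40)
  # nothing above threshold
  expect_length(buildNewGroups(mkRes(c("a", "b"), c("b", "c"), c(3, 2))),
                0L)
  # transitive chain closes into one group despite the weak a-c pair
  res <- rbind(mkRes("a", "b", 5), mkRes("b", "c", 5), mkRes("a", "c", 1))
  gr <- buildNewGroups(res)
  expect_length(gr, 1L)
  expect_setequal(gr[[1]], c("a", "b", "c"))
  # labels order groups by size then smallest member
  res2 <- rbind(res, mkRes("x", "y", 6))
  gr2 <- buildNewGroups(res2)
  expect_equal(names(gr2), c("LG1", "LG2"))
  expect_setequal(gr2$LG1, c("a", "b", "c"))
})

test_that("two hidden micro-chromosomes are recovered as two pure groups", {
  mk <- hiddenChromMarkers()
  ped <- simulateFamilyGenotypes(familyDesign(), mk, seed = 1042)
  tp <- twopointAll(ped)
  gr <- buildNewGroups(tp, markers = mk$marker, lodThreshold = 4)
  expect_length(gr, 2L)
  chromOf <- setNames(mk$chrom, mk$marker)
  purity <- vapply(gr, function(g) length(unique(chromOf[g])), 1L)
  expect_true(all(purity == 1L))
  expect_setequal(unname(vapply(gr, function(g) unique(chromOf[g]), "")),
                  c("new1", "new2"))
})

test_that("Kosambi transform matches closed forms and round-trips", {
  expect_equal(kosambiCm(0), 0)
  expect_equal(kosambiCm(0.1), 10.137, tolerance = 1e-3)
  expect_equal(kosambiCm(0.25), 27.465, tolerance = 1e-3)
  expect_error(kosambiCm(0.5), "theta")
  expect_error(kosambiCm(-0.01), "theta")
  th <- seq(0, 0.49, by = 0.01)
  expect_equal(kosambiTheta(kosambiCm(th)), th, tolerance = 1e-10)
})

test_that("orderGroup recovers marker order from two-point distances", {
  # three markers with additive thetas
  res3 <- data.frame(marker_a = c("a", "b", "a"),
                     marker_b = c("b", "c", "c"),
                     theta = c(0.05, 0.05, 0.10),
                     lod = c(8, 8, 6), n_informative = 100)
  ord3 <- orderGroup(c("a", "b", "c"), res3)
  expect_true(identical(ord3$marker, c("a", "b", "c")) ||
              identical(ord3$marker, c("c", "b", "a")))
  expect_equal(ord3$cm_prev[-1], kosambiCm(c(0.05, 0.05)), tolerance = 1e-9)

  # a 10-marker group at 5 cM spacing, 500 fully informative meioses:
  # sire heterozygous everywhere in known phase, dam homozygous, so every
  # offspring genotype reveals the sire gamete at every marker
  set.seed(19)
  M <- 10; n <- 500
  r <- 0.5 * (1 - exp(-0.02 * 5))       # Haldane, 5 cM
  choice <- matrix(0L, n, M)
  choice[, 1] <- sample(0:1, n, TRUE)
  for (j in 2:M)
    choice[, j] <- (choice[, j - 1] + (runif(n) < r)) %% 2L
  geno <- ifelse(choice == 0L, "AA", "AB")   # hap0 carries A, dam gives A
  markers <- sprintf("m%02d", 1:M)
  ped <- data.frame(family = "F1",
                    id = c("S", "D", sprintf("O%03d", 1:n)),
                    sire = c("0", "0", rep("S", n)),
                    dam = c("0", "0", rep("D", n)),
                    stringsAsFactors = FALSE)
  for (j in 1:M) ped[[markers[j]]] <- c("AB", "AA", geno[, j])
  tp <- twopointAll(ped)
  ord <- orderGroup(markers, tp)$marker
  expect_true(identical(ord, markers) || identical(ord, rev(markers)))

  # two-marker group: both orders equivalent, one distance
  res2 <- data.frame(marker_a = "a", marker_b = "b", theta = 0.1, lod = 5,
                     n_informative = 50)
  ord2 <- orderGroup(c("a", "b"), res2)
  expect_equal(nrow(ord2), 2L)
  expect_equal(ord2$cm_prev[2], kosambiCm(0.1))
})
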