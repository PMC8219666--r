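test_that("feature extraction is zero for uncovered sites and depth-normalized", {
  st <- LibraryStats(500, 50, 150, 30)
  empty <- mkAlnTable(pos = 1L, cigar = "150M")[0, ]
  call <- list(chrom = "chr1", leftBp = 5000L, rightBp = 5010L)
  f <- extractFeatures(call, empty, st)
  expect_length(f, 14)
  expect_equal(names(f), genotypeFeatureNames())
  ## all read-derived entries are zero (tsdLen comes from the breakpoints)
  expect_true(all(f[names(f) != "tsdLen"] == 0))

  ## doubling all counts and the depth leaves normalized entries unchanged
  s <- withr::with_seed(4, rndDna(150))
  base <- rbind(mkAlnTable(pos = rep(4901L, 6), cigar = "100M50S", seq = s),
                mkAlnTable(pos = rep(4800L, 8), cigar = "150M"))
  double <- rbind(base, base)
  double$qname <- sprintf("d%03d", seq_len(nrow(double)))
  f1 <- extractFeatures(call, base, st)
  f2 <- extractFeatures(call, double, LibraryStats(500, 50, 150, 60))
  expect_equal(f1[["clipLeftNorm"]], f2[["clipLeftNorm"]])
  expect_equal(f1[["clipRightNorm"]], f2[["clipRightNorm"]])
  expect_equal(2 * f1[["clipLeft"]], f2[["clipLeft"]])
})

test_that("a simulated heterozygous site shows mixed support", {
  fx <- fixtureShortMini()
  st <- fixtureShortMiniCalls()$stats
  truth <- fx$planted$truth
  het <- truth[truth$zygosity == "het" & truth$type == "alu", ][1, ]
  call <- list(chrom = "chr1", leftBp = het$pos - het$tsdLen,
               rightBp = het$pos)
  f <- extractFeatures(call, fx$tbl, st)
  expect_gt(f[["spanning"]], 0)
  expect_gt(f[["discRatio"]], 0)
  expect_lt(f[["discRatio"]], 1)
  expect_gt(f[["clipLeft"]] + f[["clipRight"]], 0)
})

test_that("trio labeling rules match their definitions, with strict ratio", {
  sup <- function(clip, disc = 10, conc = 1, fm = 0)
    list(clip = clip, disc = disc, concordant = conc, fullyMapped = fm)
  ## one parent called, other clean -> het
  expect_equal(labelTrainingSite("father",
                                 list(father = sup(10), mother = sup(0))), 1L)
  ## neither parent supported -> reference homozygous
  expect_equal(labelTrainingSite(character(0),
                                 list(father = sup(0), mother = sup(0))), 0L)
  ## both called, ratio 0.90, no fully mapped -> alternate homozygous
  expect_equal(labelTrainingSite(c("father", "mother"),
                                 list(father = sup(10, disc = 9, conc = 1),
                                      mother = sup(10, disc = 9, conc = 1))), 2L)
  ## ratio exactly 0.85 fails the strict inequality
  expect_true(is.na(labelTrainingSite(c("father", "mother"),
                                      list(father = sup(10, disc = 85, conc = 15),
                                           mother = sup(10, disc = 0, conc = 0)))))
  ## no silent default: one parent called but other has clips
  expect_true(is.na(labelTrainingSite("father",
                                      list(father = sup(10), mother = sup(2)))))
})

test_that("the classifier separates separable classes and not shuffled ones", {
  withr::with_seed(31, {
    n <- 120
    feats <- rbind(matrix(rnorm(n * 14, 0), ncol = 14),
                   matrix(rnorm(n * 14, 6), ncol = 14),
                   matrix(rnorm(n * 14, 12), ncol = 14))
    labels <- rep(0:2, each = n)
    m <- trainGenotyper(feats, labels, seed = 1)
    expect_equal(m$heldOutAccuracy, 1)
    shuffled <- sample(labels)
    m2 <- trainGenotyper(feats, shuffled, seed = 1)
    expect_lt(abs(m2$heldOutAccuracy - 1 / 3), 0.1)
  })
})

test_that("training requires all three classes and flags the missing one", {
  feats <- matrix(rnorm(50 * 14), ncol = 14)
  expect_error(trainGenotyper(feats, rep(c(0L, 1L), 25), seed = 1), "2")
})

test_that("prediction is deterministic, memorizes tiny sets, checks schema", {
  gs <- simulateGenotypeSites(40L, 30, seed = 5)
  m <- trainGenotyper(gs$features, gs$labels, trainFraction = 0.99, seed = 2)
  p1 <- predictGenotype(m, gs$features[m$trainIdx, ])
  expect_equal(p1, gs$labels[m$trainIdx])        # memorization on train set
  p2 <- predictGenotype(m, gs$features[m$trainIdx, ])
  expect_identical(p1, p2)                       # deterministic
  expect_equal(predictGenotype(m, rep(0, 14)), 0L)
  expect_error(predictGenotype(m, rep(0, 13)), "schema")
})

test_that("Mendelian consistency equals the allele-transmission oracle", {
  n_incons <- 0L
  for (f in 0:2) for (m in 0:2) for (c in 0:2) {
    got <- checkMendelianConsistency(f, m, c)
    expect_equal(got, mendelianOracle(f, m, c),
                 info = sprintf("F=%d M=%d C=%d", f, m, c))
    if (!got) n_incons <- n_incons + 1L
  }
  expect_equal(n_incons, 12L)
  ## the worked case: both parents homozygous, het child is inconsistent
  expect_false(checkMendelianConsistency(2, 2, 1))
  expect_true(checkMendelianConsistency(0, 0, 0))
})

test_that("genotype predictions on Mendelian trios are consistent", {
  gs <- simulateGenotypeSites(200L, 30, seed = 6)
  m <- trainGenotyper(gs$features, gs$labels, seed = 6)
  tr <- simulateTrioSites(120L, 30, seed = 8)
  pf <- predictGenotype(m, tr$features$F)
  pm <- predictGenotype(m, tr$features$M)
  pc <- predictGenotype(m, tr$features$C)
  cons <- mapply(checkMendelianConsistency, pf, pm, pc)
  expect_gte(mean(cons), 0.95)
})
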