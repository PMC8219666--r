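test_that("clip stacks above threshold become candidates, below do not", {
  thr <- list(minClipReads = 3L, minDiscReads = 3L,
              maxRefDivergencePct = 5, clonality = 1)
  seq5 <- withr::with_seed(2, rndDna(150))
  five <- mkAlnTable(pos = rep(851L, 5), cigar = "100M50S", seq = seq5)
  cands <- collectClipCandidates(five, thr)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$site, 950L)       # last aligned base
  expect_equal(cands[[1]]$countR, 5L)
  two <- mkAlnTable(pos = rep(851L, 2), cigar = "100M50S", seq = seq5)
  expect_length(collectClipCandidates(two, thr), 0)
})

test_that("candidate discovery recovers planted insertion breakpoints", {
  fx <- fixtureShortMini()
  st <- estimateLibraryStats(fx$tbl)
  cands <- collectClipCandidates(fx$tbl, autoThresholds(st))
  sites <- vapply(cands, function(x) x$site, 0L)
  for (p in fx$planted$truth$pos)
    expect_lte(min(abs(sites - p)), 3L)
})

test_that("MAPQ-0 and duplicate reads contribute no clip evidence", {
  thr <- list(minClipReads = 2L, minDiscReads = 2L,
              maxRefDivergencePct = 5, clonality = 1)
  s <- withr::with_seed(3, rndDna(150))
  t1 <- mkAlnTable(pos = rep(1000L, 4), cigar = "100M50S", seq = s, mapq = 0L)
  expect_length(collectClipCandidates(t1, thr), 0)
  t2 <- mkAlnTable(pos = rep(1000L, 4), cigar = "100M50S", seq = s,
                   flag = 99L + 1024L)
  expect_length(collectClipCandidates(t2, thr), 0)
})

test_that("consensus profiles localize clips and mates on the consensus", {
  lib <- fixtureLibrary()
  alu <- as.character(consensusSeqs(lib)[["AluYa5"]])
  ## clips from the element tail, mates from the head
  cand <- list(seqsR = replicate(5, substr(alu, 1, 60)),
               seqsL = replicate(5, substr(alu, 241, 300)),
               anchorR = 1000L, anchorL = 1000L, countR = 5L, countL = 5L,
               site = 1000L, chrom = "chr1")
  prof <- buildConsensusProfile(cand,
                                discLeft = replicate(4, substr(alu, 1, 150)),
                                discRight = replicate(4, substr(alu, 151, 300)),
                                library = lib)
  expect_equal(prof$family, "Alu")
  expect_lt(abs(prof$c1$center - 30), 15)
  expect_lt(abs(prof$c2$center - 270), 15)
  expect_lt(abs(prof$d2$center - 75), 30)
  expect_lt(abs(prof$d1$center - 225), 30)
})

test_that("scattered clipped sequences fail the single-breakpoint condition", {
  lib <- fixtureLibrary()
  l1 <- as.character(consensusSeqs(lib)[["L1HS"]])
  starts <- seq(1, 5400, length.out = 10)
  cand <- list(seqsR = vapply(starts, function(s)
    substr(l1, s, s + 99), ""), seqsL = character(0),
    anchorR = 1000L, anchorL = NA_integer_, countR = 10L, countL = 0L,
    site = 1000L, chrom = "chr1")
  prof <- buildConsensusProfile(cand, library = lib)
  expect_lt(prof$c1$size, 0.8 * prof$c1$total)
  st <- LibraryStats(500, 50, 150, 30)
  verdict <- checkProfileConsistency(prof, st)
  expect_false(verdict$pass)
  expect_match(verdict$reason, "scatter")
})

test_that("profile consistency applies the mu + 3 sigma gate", {
  st <- LibraryStats(500, 50, 150, 30)
  mkProf <- function(c1, c2, d1, d2) {
    cl <- function(x) if (is.null(x)) NULL else
      list(center = x, span = 10, size = 10, total = 10)
    list(subfamily = "AluYa5", family = "Alu", c1 = cl(c1), c2 = cl(c2),
         d1 = cl(d1), d2 = cl(d2), orientation = "+")
  }
  expect_true(checkProfileConsistency(mkProf(0, 1000, 360, 300), st)$pass)
  expect_false(checkProfileConsistency(mkProf(0, 1000, 1000, 651), st)$pass)
  expect_true(checkProfileConsistency(mkProf(0, 1000, 1000, 650), st)$pass)
})

test_that("random profiles agree with a brute-force consistency recheck", {
  st <- LibraryStats(500, 50, 150, 30)
  gate <- 500 + 3 * 50
  withr::with_seed(77, {
    for (k in 1:200) {
      centers <- sample(0:1500, 4, replace = TRUE)
      sizes <- sample(1:20, 4, replace = TRUE)
      totals <- sizes + sample(0:6, 4, replace = TRUE)
      present <- runif(4) < 0.8
      prof <- list(subfamily = "x", family = "x", orientation = "+")
      nm <- c("c1", "c2", "d1", "d2")
      for (i in 1:4)
        prof[[nm[i]]] <- if (present[i])
          list(center = centers[i], span = 10, size = sizes[i],
               total = totals[i]) else NULL
      got <- checkProfileConsistency(prof, st)$pass
      want <- TRUE
      for (cc in c("c1", "c2"))
        if (!is.null(prof[[cc]]) &&
            prof[[cc]]$size < 0.8 * prof[[cc]]$total) want <- FALSE
      if (want)
        for (p in list(c("c1", "d2"), c("c2", "d1"))) {
          a <- prof[[p[1]]]; b <- prof[[p[2]]]
          if (!is.null(a) && !is.null(b) &&
              abs(a$center - b$center) > gate) want <- FALSE
        }
      expect_equal(got, want, info = sprintf("profile %d", k))
    }
  })
})

test_that("the divergence filter drops same-family low-divergence overlaps", {
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(900L, 5000L), c(1200L, 5300L)))
  S4Vectors::mcols(ann) <- S4Vectors::DataFrame(
    family = c("Alu", "L1"), subfamily = c("AluY", "L1PA"),
    divergencePct = c(1.5, 1.5), isFullLength = NA)
  expect_false(divergenceFilter("chr1", 1000L, "Alu", ann, 5))  # drop
  expect_true(divergenceFilter("chr1", 5100L, "Alu", ann, 5))   # other family
  S4Vectors::mcols(ann)$divergencePct[1] <- 12
  expect_true(divergenceFilter("chr1", 1000L, "Alu", ann, 5))   # diverged
})

test_that("TSD and polyA follow the anchor conventions", {
  refSeq <- withr::with_seed(8, rndDna(2000))
  cand <- list(anchorL = 1000L, anchorR = 1012L,
               seqsR = strrep("G", 30),
               seqsL = paste0(strrep("C", 20), strrep("A", 10)),
               site = 1012L, chrom = "chr1")
  sig <- detectTsdPolyA(cand, refSeq)
  expect_equal(sig$tsdLen, 12L)
  expect_equal(sig$tsdSeq, substr(refSeq, 1001, 1012))
  expect_equal(sig$polyALen, 10L)
  ## equal anchors: no duplication
  cand$anchorR <- 1000L
  expect_equal(detectTsdPolyA(cand, refSeq)$tsdLen, 0L)
})

test_that("target-site deletions are resolved from depth and bounded below", {
  fx <- fixtureShortMini()
  truth <- fx$planted$truth
  tsdel <- truth[truth$type == "target_site_deletion", ]
  cand <- list(site = tsdel$pos, chrom = "chr1")
  second <- resolveTargetSiteDeletion(cand, fx$tbl)
  expect_false(is.na(second))
  expect_lt(abs(second - tsdel$spanEnd), 25)
  ## flat depth in a quiet region -> no second breakpoint
  quiet <- list(site = 20000L, chrom = "chr1")
  expect_true(is.na(resolveTargetSiteDeletion(quiet, fx$tbl)))
})

test_that("short plateaus below 50 bp are ignored", {
  ## constructed coverage: 30X everywhere except a 40 bp dip
  reads <- mkAlnTable(pos = seq(1L, 6000L, by = 5L), cigar = "150M")
  dipReads <- reads[!(reads$pos > 2950 & reads$pos < 3000), ]
  cand <- list(site = 2950L, chrom = "chr1")
  expect_true(is.na(resolveTargetSiteDeletion(cand, dipReads,
                                              minPlateau = 50L)))
})

test_that("end-to-end short-read calling recovers the planted events", {
  fx <- fixtureShortMini()
  calls <- fixtureShortMiniCalls()$calls
  s <- scoreAgainstTruth(calls, fx$planted$truth)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 1)
  df <- as.data.frame(calls)
  truth <- fx$planted$truth
  ## transduction events annotated with their source locus
  tdTruth <- truth[truth$type == "transduction_canonical", ]
  j <- which.min(abs(df$start - tdTruth$pos))
  expect_equal(df$tdKind[j], "canonical")
  expect_equal(df$tdStart[j], tdTruth$srcStart)
  orTruth <- truth[truth$type == "transduction_orphan", ]
  j <- which.min(abs(df$start - orTruth$pos))
  expect_equal(df$tdKind[j], "orphan")
  ## TSDs match the planted lengths at two-sided sites
  twoSided <- truth$type %in% c("alu", "l1_trunc")
  for (i in which(twoSided)) {
    j <- which.min(abs(df$start - truth$pos[i]))
    expect_equal(df$tsdLen[j], truth$tsdLen[i])
  }
})

test_that("alignments with no clipped reads yield no calls", {
  fx <- fixtureShortMini()
  clean <- fx$tbl[fx$tbl$clipL == 0L & fx$tbl$clipR == 0L & fx$tbl$isMapped, ]
  st <- estimateLibraryStats(clean)
  calls <- callInsertionsShort(clean, fx$genome, fx$ref$library,
                               fx$ref$rmsk, stats = st)
  expect_length(calls, 0)
})

test_that("per-chromosome sharding reproduces the joint run", {
  ## two small chromosomes, called jointly and separately
  build <- function(seed, chromName) {
    cfg <- simConfig(seed = seed, genomeLength = 250000L,
                     events = data.frame(type = "alu", count = 2L))
    ref <- simulateReference(cfg)
    planted <- plantInsertions(ref)
    tbl <- simulateShortReads(ref, planted)
    tbl$chrom <- chromName; tbl$mchrom <- chromName
    list(ref = ref, tbl = tbl)
  }
  a <- fixtureCached("shardA", function() build(21L, "chr1"))
  b <- fixtureCached("shardB", function() build(22L, "chr2"))
  genome <- Biostrings::DNAStringSet(c(a$ref$seq, b$ref$seq))
  names(genome) <- c("chr1", "chr2")
  lib <- a$ref$library
  st <- estimateLibraryStats(a$tbl)
  joint <- rbind(a$tbl, b$tbl)
  callsJoint <- callInsertionsShort(joint, genome, lib, NULL, stats = st)
  calls1 <- callInsertionsShort(a$tbl, genome, lib, NULL, stats = st)
  calls2 <- callInsertionsShort(b$tbl, genome, lib, NULL, stats = st)
  merged <- InsertionCallSet(suppressWarnings(
    c(insertionCalls(calls1), insertionCalls(calls2))))
  expect_equal(as.data.frame(callsJoint), as.data.frame(merged))
})
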