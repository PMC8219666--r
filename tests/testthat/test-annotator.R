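test_that("L1 structural categories are classified correctly on all 25 contigs", {
  lib <- fixtureLibrary()
  cons <- as.character(consensusSeqs(lib)[["L1HS"]])
  results <- fixtureCached("l1Struct25", function() {
    vapply(l1StructureCases(), function(cs)
      annotateL1Structure(cs$seq, cons)$category, "")
  })
  wanted <- vapply(l1StructureCases(), `[[`, "", "category")
  expect_equal(unname(results), wanted)
})

test_that("the internal-deletion boundary at 20 bp is strict", {
  lib <- fixtureLibrary()
  cons <- as.character(consensusSeqs(lib)[["L1HS"]])
  n <- nchar(cons)
  gap20 <- paste0(substr(cons, 1, 3000), substr(cons, 3021, n))
  gap21 <- paste0(substr(cons, 1, 3000), substr(cons, 3022, n))
  expect_equal(annotateL1Structure(gap20, cons)$category, "full_length")
  got21 <- annotateL1Structure(gap21, cons)
  expect_equal(got21$category, "internal_deletion")
  expect_equal(got21$deletionGap, 21L)
})

test_that("unalignable sequences are an error, not a category", {
  lib <- fixtureLibrary()
  cons <- as.character(consensusSeqs(lib)[["L1HS"]])
  expect_error(annotateL1Structure(withr::with_seed(31, rndDna(500)), cons),
               "align")
})

test_that("pseudogene detection needs exons, polyA and unique hits", {
  fx <- fixtureShortMini()
  tmp <- tempfile(fileext = ".bed")
  writeExonsBed(fx$ref$transcripts, tmp)
  exonIndex <- readExonsBed(tmp, fx$genome)
  g1 <- exonIndex[exonIndex$gene == "GENE1", ]
  insertion <- paste0(paste(g1$seq, collapse = ""), strrep("A", 25))
  got <- detectPseudogene(insertion, exonIndex)
  expect_equal(got$gene, "GENE1")
  expect_equal(nrow(got$exons), nrow(g1))
  expect_gte(got$polyALen, 20)

  ## without the polyA tail there is no call
  noTail <- paste(g1$seq, collapse = "")
  expect_null(detectPseudogene(noTail, exonIndex))

  ## a duplicated exon (zero uniqueness) drops coverage below the gate
  dupIndex <- rbind(exonIndex,
                    transform(g1, gene = "GENE1_PARA"))
  short2 <- paste0(g1$seq[1], g1$seq[2], strrep("A", 25))
  expect_null(detectPseudogene(short2, dupIndex))

  ## an exon chain spanning two genes is rejected
  g2 <- exonIndex[exonIndex$gene == "GENE2", ]
  chimera <- paste0(g1$seq[1], g2$seq[1], g2$seq[2], strrep("A", 25))
  expect_null(detectPseudogene(chimera, exonIndex))
})

test_that("breakpoint pairing is reciprocal and symmetric", {
  refSeq <- withr::with_seed(32, rndDna(30000))
  lib <- fixtureLibrary()
  te <- as.character(consensusSeqs(lib)[["AluYa5"]])
  A <- 10000L; B <- 15000L          # TE-mediated deletion geometry
  ## contig of the right-clip breakpoint at A: TE + reference after B
  rightContig <- paste0(te, substr(refSeq, B + 1L, B + 1500L))
  ## contig of the left-clip breakpoint at B: reference before A + TE
  leftContig <- paste0(substr(refSeq, A - 1499L, A), te)
  pairs <- pairSvBreakpoints(leftBps = B, rightBps = A, refSeq = refSeq,
                             leftContigs = list(leftContig),
                             rightContigs = list(rightContig))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$leftBp, B)
  expect_equal(pairs$rightBp, A)

  ## one-way alignment only -> no pair
  badLeft <- withr::with_seed(33, rndDna(1800))
  none <- pairSvBreakpoints(B, A, refSeq, list(badLeft), list(rightContig))
  expect_equal(nrow(none), 0L)
})

test_that("deletion is never called when the flank gap is below 100 bp", {
  refSeq <- withr::with_seed(34, rndDna(20000))
  lib <- fixtureLibrary()
  te <- as.character(consensusSeqs(lib)[["AluYa5"]])
  A <- 10000L
  for (gap in c(20L, 60L, 99L)) {
    contig <- paste0(substr(refSeq, A - 999L, A), te,
                     substr(refSeq, A + gap + 1L, A + gap + 1000L))
    got <- classifyTeMediatedSv(rightClipBp = A, leftClipBp = A + gap,
                                contig = contig, refSeq = refSeq,
                                library = lib)
    expect_true(got$svType != "deletion", info = paste("gap", gap))
  }
  ## and a 150 bp gap is a deletion
  contig <- paste0(substr(refSeq, A - 999L, A), te,
                   substr(refSeq, A + 151L, A + 1150L))
  got <- classifyTeMediatedSv(A, A + 150L, contig, refSeq, lib)
  expect_equal(got$svType, "deletion")
  expect_equal(got$spanStart, A + 1L)
  expect_equal(got$spanEnd, A + 150L)
})

test_that("duplication geometry classifies from the same-interval condition", {
  refSeq <- withr::with_seed(35, rndDna(30000))
  lib <- fixtureLibrary()
  te <- as.character(consensusSeqs(lib)[["AluYb8"]])
  A <- 12000L; B <- 14000L          # duplicated interval [A, B]
  contig <- paste0(substr(refSeq, A - 999L, B), te,
                   substr(refSeq, A + 1L, B + 1000L))
  got <- classifyTeMediatedSv(rightClipBp = B, leftClipBp = A,
                              contig = contig, refSeq = refSeq,
                              library = lib)
  expect_equal(got$svType, "duplication")
  expect_equal(got$teFamily, "Alu")
})

test_that("ghost clusters without satellite flanks are not reported", {
  fx <- fixtureCached("ghostNeg", function() {
    ## donor-mapped both-side-clipped reads whose flanks are unique
    ## (non-satellite) sequence
    cfg <- simConfig(seed = 41L, genomeLength = 200000L, nFullL1 = 1L,
                     satelliteBlocks = data.frame(class = character(0),
                                                  length = integer(0)),
                     events = data.frame(type = "alu", count = 1L))
    ref <- simulateReference(cfg)
    donor <- ref$fullL1s[1]
    lib <- ref$library
    l1 <- as.character(consensusSeqs(lib)[["L1HS"]])
    withr::with_seed(42, {
      fl <- rndDna(1200); fr <- rndDna(1200)
      rows <- lapply(1:5, function(i) {
        data.frame(qname = sprintf("gr%d", i), flag = 0L, chrom = "chr1",
                   pos = GenomicRanges::start(donor), mapq = 60L,
                   cigar = sprintf("%dS%dM%dS", 1200L, 6000L, 1200L),
                   mchrom = NA, mpos = 0L, tlen = 0L,
                   seq = paste0(fl, l1, fr))
      })
    })
    list(tbl = alignmentTable(do.call(rbind, rows)), donor = donor,
         lib = lib)
  })
  res <- findGhostL1(fx$tbl, fx$donor, fx$lib)
  expect_length(res, 0)                      # not reported as ghost
  expect_equal(attr(res, "nClusters"), 1L)   # but the cluster formed
})

test_that("a single read at a donor forms no cluster", {
  fx <- fixtureCached("ghostNeg", function() stop("built above"))
  one <- fx$tbl[1, ]
  res <- findGhostL1(one, fx$donor, fx$lib)
  expect_length(res, 0)
  expect_equal(attr(res, "nClusters"), 0L)
})
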