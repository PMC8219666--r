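test_that("CIGAR insertions and clips become events; short clips do not", {
  seq300 <- withr::with_seed(13, rndDna(2300))
  tbl <- mkAlnTable(pos = 5001L, cigar = "1000M300I1000M", seq = seq300,
                    flag = 0L)
  ev <- harvestBreakpointEvidence(tbl)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "internal-insertion")
  expect_equal(ev$segmentLen, 300L)
  expect_equal(ev$anchor, 6000L)              # last base before the insertion
  expect_equal(ev$segment, substr(seq300, 1001, 1300))

  small <- mkAlnTable(pos = 5001L, cigar = "20S1000M",
                      seq = withr::with_seed(14, rndDna(1020)), flag = 0L)
  expect_equal(nrow(harvestBreakpointEvidence(small)), 0L)
})

test_that("reads without stored sequence are skipped with a warning", {
  tbl <- mkAlnTable(pos = 5001L, cigar = "100S1000M", seq = NA, flag = 0L)
  expect_warning(ev <- harvestBreakpointEvidence(tbl), "skipped")
  expect_equal(nrow(ev), 0L)
})

test_that("clip grouping matches the hand-computed median and dispersion", {
  ev <- data.frame(qname = sprintf("r%d", 1:4), chrom = "chr1",
                   anchor = c(1000L, 1005L, 1010L, 1120L),
                   kind = "right-clip", segment = "ACGT", segmentLen = 4L,
                   row = 1:4, qstart = 1L, qend = 4L)
  gr <- groupClipEvents(ev, window = 75L, maxDispersion = 45L)
  expect_length(gr, 2)
  expect_equal(gr[[1]]$medianSite, 1005L)
  expect_equal(gr[[1]]$dispersion, sqrt(mean(c(25, 0, 25))), tolerance = 1e-9)
  expect_equal(gr[[2]]$size, 1L)
  expect_equal(gr[[2]]$dispersion, 0)

  ## a widely scattered chain is rejected by the dispersion gate
  wide <- data.frame(qname = sprintf("w%d", 1:9), chrom = "chr1",
                     anchor = seq(0L, 400L, by = 50L), kind = "right-clip",
                     segment = "ACGT", segmentLen = 4L, row = 1:9,
                     qstart = 1L, qend = 4L)
  gw <- groupClipEvents(wide, window = 75L, maxDispersion = 45L)
  expect_length(gw, 0)
  expect_equal(attr(gw, "rejected"), 1L)
})

test_that("accepted groups always satisfy the dispersion gate", {
  fx <- fixtureLongMini()
  ev <- harvestBreakpointEvidence(fx$tbl)
  for (g in groupClipEvents(ev))
    expect_lte(g$dispersion, 45)
})

test_that("the assembler reconstructs a tiled sequence exactly", {
  truthSeq <- withr::with_seed(15, rndDna(3000))
  starts <- seq(1, 2001, by = 250)
  reads <- substring(truthSeq, starts, starts + 999L)
  asm <- assembleLocal(reads, maxReads = 12L)
  expect_false(asm$failed)
  expect_equal(asm$contig, truthSeq)
})

test_that("the assembler polishes noisy reads above 98 percent identity", {
  truthSeq <- withr::with_seed(16, rndDna(4000))
  reads <- withr::with_seed(17,
    vapply(1:8, function(i) retrofind:::mutateSeqs(truthSeq, 0.05), ""))
  asm <- assembleLocal(reads)
  expect_false(asm$failed)
  expect_gte(alignPair(asm$contig, truthSeq)$identity, 98)
})

test_that("mutually unalignable read sets signal assembly failure", {
  withr::with_seed(18, {
    setA <- vapply(1:3, function(i) rndDna(1000), "")
    setB <- vapply(1:3, function(i) rndDna(990), "")
  })
  asm <- assembleLocal(c(setA, setB))
  expect_true(asm$failed)
})

test_that("assembly of error-free reads is order-invariant", {
  truthSeq <- withr::with_seed(19, rndDna(2500))
  starts <- seq(1, 1501, by = 300)
  reads <- substring(truthSeq, starts, starts + 999L)
  a <- assembleLocal(reads)
  b <- assembleLocal(rev(reads))
  cset <- withr::with_seed(20, assembleLocal(sample(reads)))
  expect_equal(a$contig, b$contig)
  expect_equal(a$contig, cset$contig)
})

test_that("insertion extraction returns the sequence between the flanks", {
  lib <- fixtureLibrary()
  refSeq <- withr::with_seed(21, rndDna(20000))
  site <- 10000L
  insSeq <- as.character(consensusSeqs(lib)[["L1HS"]])
  contig <- paste0(substr(refSeq, site - 799L, site), insSeq,
                   substr(refSeq, site + 1L, site + 800L))
  got <- extractInsertion(contig, refSeq, site)
  expect_equal(got$insertionSeq, insSeq)
  expect_equal(got$refinedLeftBp, site)
  expect_equal(got$refinedRightBp, site)
  ## contiguous flanks (no insertion)
  noIns <- paste0(substr(refSeq, site - 799L, site),
                  substr(refSeq, site + 1L, site + 800L))
  expect_null(extractInsertion(noIns, refSeq, site))
  ## missing right flank -> unresolved
  oneFlank <- paste0(substr(refSeq, site - 799L, site), insSeq)
  expect_null(extractInsertion(oneFlank, refSeq, site))
  ## reverse-complement contigs resolve identically
  gotRc <- extractInsertion(rcStr(contig), refSeq, site)
  expect_equal(gotRc$insertionSeq, insSeq)
  expect_true(gotRc$flipped)
})

test_that("family annotation reports residual unaligned segments", {
  lib <- fixtureLibrary()
  alu <- as.character(consensusSeqs(lib)[["AluYb8"]])
  ann <- annotateTeFamily(paste0(alu, strrep("A", 20)), lib)
  expect_equal(ann$subfamily, "AluYb8")
  expect_length(ann$residuals, 0)          # a 20 bp polyA is no residual

  l1 <- as.character(consensusSeqs(lib)[["L1HS"]])
  tail800 <- withr::with_seed(22, rndDna(800))
  ann2 <- annotateTeFamily(paste0(substr(l1, 3001, 6000), tail800), lib)
  expect_equal(ann2$family, "L1")
  expect_length(ann2$residuals, 1)
  expect_gte(nchar(ann2$residuals), 750)

  rnd <- withr::with_seed(23, rndDna(400))
  expect_equal(annotateTeFamily(rnd, lib)$family, "unknown")
})

test_that("long-read transduction tracing requires a unique flank hit", {
  fx <- fixtureLongMini()
  lib <- fx$ref$library
  fs <- flankSeqs(lib)
  residual <- substr(as.character(fs[[1]]), 1, 600)
  hit <- traceTransductionLr(residual, lib)
  expect_equal(hit$kind, "canonical")
  expect_equal(hit$srcStart, GenomicRanges::start(flankIndex(lib))[1])

  ## duplicate windows -> ambiguous -> none
  fi2 <- c(flankIndex(lib)[1], flankIndex(lib)[1])
  S4Vectors::mcols(fi2)$sourceId <- c("a", "b")
  dupLib <- ConsensusLibrary(consensusSeqs(lib), lib@family,
                             flankIndex = fi2,
                             flankSeqs = setNames(c(fs[1], fs[1]), c("a", "b")))
  expect_equal(traceTransductionLr(residual, dupLib)$kind, "none")

  expect_equal(traceTransductionLr(strrep("A", 200), lib)$kind, "none")
})

test_that("hybrid merging keeps long-read breakpoints and the union", {
  mk <- function(pos, prov, insSeq = NA_character_) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      family = "Alu", provenance = prov, insSeq = insSeq,
      tsdSeq = ifelse(prov == "short", "ACGT", ""),
      tsdLen = ifelse(prov == "short", 4L, 0L))
    InsertionCallSet(gr)
  }
  shortCalls <- InsertionCallSet(c(insertionCalls(mk(1000L, "short")),
                                   insertionCalls(mk(9000L, "short"))))
  longCalls <- mk(1003L, "long", "ACGTACGT")
  merged <- mergeHybridCandidates(shortCalls, longCalls)
  df <- as.data.frame(merged)
  expect_equal(nrow(df), 2L)
  hyb <- df[df$provenance == "hybrid", ]
  expect_equal(hyb$start, 1003L)           # long-read breakpoint kept
  expect_equal(hyb$tsdLen, 4L)             # short-read TSD carried over
  expect_true(any(df$start == 9000L & df$provenance == "short"))
})

test_that("end-to-end long-read calling recovers the mini scenario", {
  fx <- fixtureLongMini()
  calls <- fixtureCached("longMiniCalls", function()
    callInsertionsLong(fx$tbl, fx$genome, fx$ref$library))
  s <- scoreAgainstTruth(calls, fx$planted$truth)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 1)
  df <- as.data.frame(calls)
  for (i in seq_len(nrow(df))) {
    tr <- fx$planted$truth[which.min(abs(fx$planted$truth$pos - df$start[i])), ]
    expect_gte(alignPair(df$insSeq[i], tr$insSeq)$identity, 98)
  }
  ## refined breakpoints are exact on these events
  errs <- vapply(seq_len(nrow(df)), function(i)
    min(abs(fx$planted$truth$pos - df$start[i])), 0)
  expect_true(all(errs <= 1))
})
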