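## helper: a one-call set at a given site
oneCall <- function(pos, leftBp = pos, rightBp = pos) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    family = "Alu", subfamily = "AluYa5",
    leftBp = leftBp, rightBp = rightBp)
  InsertionCallSet(gr)
}

## helper: control table with a given depth and clip support at a site
controlTbl <- function(site, depth, clips, clipSeq = NULL) {
  rl <- 150L
  covReads <- mkAlnTable(pos = seq(site - 800L, site + 800L,
                                   by = max(1L, as.integer(2 * rl / depth))),
                         cigar = "150M")
  if (clips > 0) {
    cs <- if (is.null(clipSeq)) strrep("G", 50) else clipSeq
    clipReads <- mkAlnTable(pos = rep(site - 99L, clips),
                            cigar = "100M50S", seq = cs,
                            qname = sprintf("c%03d", seq_len(clips)))
    covReads <- rbind(covReads, clipReads)
  }
  covReads[order(covReads$pos), ]
}

test_that("somatic status follows the depth-scaled allowance", {
  st <- LibraryStats(500, 50, 150, 30)
  ## clean 40X control -> somatic
  res <- callSomatic(oneCall(5000L), controlTbl(5000L, 40, 0), st)
  expect_equal(res$status, "somatic")
  ## 6 control clips at 30X: allowance 1, 6 > 3 -> germline
  res <- callSomatic(oneCall(5000L), controlTbl(5000L, 30, 6), st)
  expect_equal(res$status, "germline")
  expect_equal(res$controlClip, 6L)
  ## 2X control coverage -> ambiguous, flagged low coverage
  res <- callSomatic(oneCall(5000L), controlTbl(5000L, 2, 0), st)
  expect_equal(res$status, "ambiguous")
  expect_true(res$lowCoverage)
})

test_that("clonality 1 rescanning equals the germline caller", {
  fx <- fixtureShortMini()
  st <- fixtureShortMiniCalls()$stats
  base <- fixtureShortMiniCalls()$calls
  rescan <- rescanLowClonality(fx$tbl, fx$genome, fx$ref$library,
                               fx$ref$rmsk, clonality = 1, stats = st)
  expect_equal(as.data.frame(rescan), as.data.frame(base))
})

test_that("lowering clonality never removes a call (monotonicity)", {
  fx <- fixtureShortMini()
  st <- fixtureShortMiniCalls()$stats
  c50 <- rescanLowClonality(fx$tbl, fx$genome, fx$ref$library,
                            fx$ref$rmsk, clonality = 0.5, stats = st)
  c25 <- rescanLowClonality(fx$tbl, fx$genome, fx$ref$library,
                            fx$ref$rmsk, clonality = 0.25, stats = st)
  p50 <- GenomicRanges::start(insertionCalls(c50))
  p25 <- GenomicRanges::start(insertionCalls(c25))
  expect_true(all(p50 %in% p25))
})
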