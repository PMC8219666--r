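test_that("RepeatMasker .out rows parse with exact coordinates", {
  tmp <- tempfile(fileext = ".out")
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1001L, 5000L), c(1100L, 5999L)),
                               strand = c("+", "-"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    family = c("Alu", "L1"), subfamily = c("AluYa5", "L1HS"),
    divergencePct = c(1.5, 12.0), isFullLength = NA)
  writeRepeatmaskerOut(gr, tmp)
  back <- parseRepeatmaskerOut(tmp)
  expect_equal(GenomicRanges::start(back), c(1001L, 5000L))
  expect_equal(GenomicRanges::end(back), c(1100L, 5999L))
  expect_equal(S4Vectors::mcols(back)$family, c("Alu", "L1"))
  expect_equal(S4Vectors::mcols(back)$subfamily, c("AluYa5", "L1HS"))
  expect_equal(S4Vectors::mcols(back)$divergencePct, c(1.5, 12.0))
  expect_equal(as.character(GenomicRanges::strand(back)), c("+", "-"))
})

test_that(".out parsing handles empty files and flags malformed rows", {
  tmp <- tempfile(fileext = ".out")
  writeLines(c("h1", "h2", ""), tmp)
  expect_length(parseRepeatmaskerOut(tmp), 0)
  writeLines(c("h1", "h2", "", "only three fields"), tmp)
  expect_error(parseRepeatmaskerOut(tmp), "line 4")
})

test_that("simulator-written .out rows round-trip the simulator truth", {
  fx <- fixtureShortMini()
  tmp <- tempfile(fileext = ".out")
  writeRepeatmaskerOut(fx$ref$rmsk, tmp)
  back <- parseRepeatmaskerOut(tmp)
  expect_equal(length(back), length(fx$ref$rmsk))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(fx$ref$rmsk))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(fx$ref$rmsk))
  expect_equal(S4Vectors::mcols(back)$family,
               S4Vectors::mcols(fx$ref$rmsk)$family)
  expect_equal(S4Vectors::mcols(back)$divergencePct,
               S4Vectors::mcols(fx$ref$rmsk)$divergencePct)
  ## full-length flags recompute identically after the round trip
  back <- annotateFullLength(back, fx$ref$library)
  expect_equal(S4Vectors::mcols(back)$isFullLength,
               S4Vectors::mcols(fx$ref$rmsk)$isFullLength)
})

test_that("BED12 exon annotations round-trip", {
  fx <- fixtureShortMini()
  tmp <- tempfile(fileext = ".bed")
  writeExonsBed(fx$ref$transcripts, tmp)
  idx <- readExonsBed(tmp, fx$genome)
  expect_equal(nrow(idx), sum(lengths(fx$ref$transcripts$exonStarts)))
  i <- 1L
  expect_equal(idx$start[idx$gene == "GENE1"][1],
               fx$ref$transcripts$exonStarts[[1]][1])
  ## exon sequences match the genome
  expect_equal(idx$seq[i],
               as.character(Biostrings::subseq(fx$genome[[idx$chrom[i]]],
                                               idx$start[i], idx$end[i])))
})

test_that("SAM written by the package reads back through Rsamtools", {
  fx <- fixtureShortMini()
  sub <- fx$tbl[fx$tbl$isMapped, ][1:500, ]
  tmp <- tempfile(fileext = ".sam")
  writeSam(sub, fx$ref$refLens, tmp)
  back <- readAlignments(tmp)
  expect_equal(nrow(back), 500L)
  o1 <- order(sub$pos, sub$qname); o2 <- order(back$pos, back$qname)
  expect_equal(back$pos[o2], sub$pos[o1])
  expect_equal(back$cigar[o2], sub$cigar[o1])
  expect_equal(back$flag[o2], sub$flag[o1])
  expect_equal(back$clipL[o2], sub$clipL[o1])
})

test_that("VCF output is grammatical and round-trips call fields", {
  fx <- fixtureShortMini()
  ## empty call set -> valid header-only VCF
  tmp <- tempfile(fileext = ".vcf")
  writeInsertionVcf(InsertionCallSet(), fx$ref$refLens, tmp)
  expect_length(readInsertionVcf(tmp), 0)
  vcf <- VariantAnnotation::readVcf(tmp, genome = "sim")
  expect_equal(nrow(vcf), 0L)

  calls <- fixtureShortMiniCalls()$calls
  gr <- insertionCalls(calls)
  S4Vectors::mcols(gr)$genotype <- rep(c("0/1", "1/1"), length.out = length(gr))
  S4Vectors::mcols(gr)$gq <- rep(0.97, length(gr))
  calls <- InsertionCallSet(gr)
  writeInsertionVcf(calls, fx$ref$refLens, tmp)
  vcf <- VariantAnnotation::readVcf(tmp, genome = "sim")
  expect_equal(nrow(vcf), length(calls))
  expect_true(all(grepl("^<INS:ME:", unlist(VariantAnnotation::alt(vcf)))))

  back <- readInsertionVcf(tmp)
  expect_equal(length(back), length(calls))
  a <- as.data.frame(calls); b <- as.data.frame(back)
  for (col in c("seqnames", "start", "family", "subfamily", "leftBp",
                "rightBp", "orientation", "tsdSeq", "tsdLen", "polyALen",
                "polyASide", "tdKind", "tdChrom", "tdStart", "tdEnd",
                "clipLeft", "clipRight", "disc", "spanning",
                "tsdelStart", "tsdelEnd", "genotype", "gq", "provenance"))
    expect_equal(b[[col]], a[[col]], info = col)
})

test_that("VCF writing rejects calls on unknown chromosomes", {
  gr <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(10, 10))
  expect_error(writeInsertionVcf(InsertionCallSet(gr), c(chr1 = 1000L),
                                 tempfile()), "chrZ")
})

test_that("one heterozygous call writes a GT=0/1 record", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500L, 500L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    family = "Alu", subfamily = "AluYa5", leftBp = 500L, rightBp = 512L,
    genotype = "0/1")
  tmp <- tempfile(fileext = ".vcf")
  writeInsertionVcf(InsertionCallSet(gr), c(chr1 = 10000L), tmp)
  body <- grep("^[^#]", readLines(tmp), value = TRUE)
  expect_length(body, 1L)
  expect_match(body, "<INS:ME:ALU>")
  expect_match(body, "0/1")
})
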