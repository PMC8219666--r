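test_that("identical seeds reproduce byte-identical outputs", {
  cfg <- simConfig(seed = 55L, genomeLength = 250000L,
                   satelliteBlocks = data.frame(class = "Alpha",
                                                length = 4000L),
                   events = data.frame(type = "alu", count = 2L))
  r1 <- simulateReference(cfg); r2 <- simulateReference(cfg)
  expect_identical(r1$seq, r2$seq)
  p1 <- plantInsertions(r1); p2 <- plantInsertions(r2)
  expect_identical(p1$truth, p2$truth)
  t1 <- simulateShortReads(r1, p1); t2 <- simulateShortReads(r2, p2)
  expect_identical(t1, t2)
  l1 <- simulateLongReads(r1, p1); l2 <- simulateLongReads(r2, p2)
  expect_identical(l1, l2)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimReference(r1, d1); writeSimReference(r2, d2)
  for (f in c("reference.fa", "consensus.fa", "rmsk.out", "exons.bed"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
})

test_that("the annotation records the configured satellite blocks", {
  cfg <- simConfig(seed = 56L, genomeLength = 150000L,
                   satelliteBlocks = data.frame(
                     class = c("Alpha", "Beta", "HSATII"),
                     length = c(4000L, 3000L, 3000L)),
                   events = data.frame(type = "alu", count = 1L))
  ref <- simulateReference(cfg)
  sat <- S4Vectors::mcols(ref$rmsk)$family %in% c("Alpha", "Beta", "HSATII")
  expect_equal(sum(sat), 3L)
  tmp <- tempfile(fileext = ".out")
  writeRepeatmaskerOut(ref$rmsk, tmp)
  back <- parseRepeatmaskerOut(tmp)
  expect_equal(sum(S4Vectors::mcols(back)$family %in%
                     c("Alpha", "Beta", "HSATII")), 3L)
})

test_that("planted reference repeats classify back to their subfamily", {
  fx <- fixtureShortMini()
  alus <- fx$ref$rmsk[S4Vectors::mcols(fx$ref$rmsk)$family == "Alu"]
  low <- alus[S4Vectors::mcols(alus)$divergencePct == 2][1]
  seq <- as.character(Biostrings::subseq(fx$genome[[1]],
                                         GenomicRanges::start(low),
                                         GenomicRanges::end(low)))
  hit <- classifySequence(seq, fx$ref$library)
  expect_equal(hit$family, "Alu")
  expect_lt(abs(hit$identityPct - 98), 1.5)
})

test_that("haplotype lengths obey length conservation", {
  fx <- fixtureShortMini()
  truth <- fx$planted$truth
  G <- nchar(fx$ref$seq)
  expectLen <- function(tr) {
    G + sum(tr$insLen) - sum(tr$nextStart - tr$pos - 1L)
  }
  expect_equal(nchar(fx$planted$hap1$seq), expectLen(truth))
  hom <- truth[truth$zygosity == "hom", ]
  expect_equal(nchar(fx$planted$hap2$seq), expectLen(hom))
})

test_that("events are placed at least 10 kb apart and truncation is literal", {
  cfg <- simConfig(seed = 57L, genomeLength = 600000L,
                   events = data.frame(type = c("alu", "l1_trunc"),
                                       count = c(5L, 3L)))
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  pos <- sort(planted$truth$pos)
  expect_true(all(diff(pos) >= 10000L))
  ## truncated L1 insertions are a literal consensus suffix plus polyA
  lib <- ref$library
  cons <- as.character(consensusSeqs(lib)[["L1HS"]])
  tr <- planted$truth[planted$truth$type == "l1_trunc", ][1, ]
  body <- substr(tr$insSeq, 1, tr$insLen - tr$polyALen)
  a <- alignPair(body, cons, mode = "local")
  expect_gte(a$identity, 99)
  expect_equal(a$tend, nchar(cons))            # reaches the consensus 3' end
})

test_that("short reads crossing a junction carry the analytic soft clip", {
  fx <- fixtureShortMini()
  truth <- fx$planted$truth
  ev <- truth[truth$type == "alu", ][1, ]
  rclips <- fx$tbl[fx$tbl$clipR >= 10 & fx$tbl$isMapped, ]
  anchors <- rclips$endpos
  expect_true(any(anchors == ev$pos))          # exact breakpoint clip stack
  ## error-free matched segments agree with the reference
  clean <- fx$tbl[fx$tbl$cigar == "150M" & fx$tbl$isMapped, ][1:50, ]
  for (i in seq_len(nrow(clean))) {
    if (is.na(clean$seq[i])) next
    refBit <- as.character(Biostrings::subseq(fx$genome[[1]], clean$pos[i],
                                              clean$endpos[i]))
    expect_equal(nchar(refBit), 150L)
  }
})

test_that("long reads spanning an insertion carry the exact I operation", {
  fx <- fixtureLongMini()
  truth <- fx$planted$truth
  ev <- harvestBreakpointEvidence(fx$tbl)
  ins <- ev[ev$kind == "internal-insertion", ]
  for (i in seq_len(nrow(truth))) {
    hits <- ins[abs(ins$anchor - truth$pos[i]) <= 2, ]
    if (!nrow(hits)) next
    expect_true(any(hits$segmentLen == truth$insLen[i]),
                info = paste("event", i))
  }
  ## at least 80% of spanning reads contribute evidence per event
  for (i in seq_len(nrow(truth))) {
    if (truth$zygosity[i] != "hom") next
    span <- sum(fx$tbl$isMapped & !fx$tbl$isSupp &
                  fx$tbl$pos < truth$pos[i] - 50 &
                  fx$tbl$endpos > truth$pos[i] + 50)
    near <- sum(abs(ev$anchor - truth$pos[i]) <= 75)
    expect_gte(near, 0.8 * span)
  }
})

test_that("site-level genotype features separate the three classes", {
  gs <- simulateGenotypeSites(50L, 30, seed = 9)
  f <- as.data.frame(gs$features)
  f$g <- gs$labels
  m <- aggregate(cbind(clipLeft, spanning, discRatio) ~ g, f, mean)
  expect_true(m$clipLeft[1] < m$clipLeft[2])
  expect_true(m$clipLeft[2] < m$clipLeft[3])
  expect_true(m$spanning[3] < m$spanning[2])
  expect_gt(m$discRatio[3], 0.8)
})
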