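test_that("identical and reverse-complement sequences align perfectly", {
  s <- withr::with_seed(5, rndDna(80))
  a <- alignPair(s, s)
  expect_equal(a$identity, 100)
  expect_equal(a$orientation, "+")
  expect_equal(a$qstart, 1L)
  expect_equal(a$qend, 80L)
  b <- alignPair(rcStr(s), s)
  expect_equal(b$identity, 100)
  expect_equal(b$orientation, "-")
})

test_that("alignPair scores match the dynamic-programming oracle", {
  withr::with_seed(42, {
    for (k in 1:300) {
      q <- rndDna(sample(12:40, 1))
      t <- rndDna(sample(20:60, 1))
      expect_equal(alignPair(q, t)$score, swOracleBoth(q, t),
                   info = sprintf("pair %d", k))
    }
  })
})

test_that("classifySequence labels exact, reverse and diverged copies", {
  lib <- fixtureLibrary()
  alu <- as.character(consensusSeqs(lib)[["AluYa5"]])
  hit <- classifySequence(alu, lib)
  expect_equal(hit$family, "Alu")
  expect_equal(hit$subfamily, "AluYa5")
  expect_equal(hit$identityPct, 100)
  expect_equal(hit$queryCoveragePct, 100)
  expect_equal(hit$orientation, "+")

  l1 <- as.character(consensusSeqs(lib)[["L1HS"]])
  revhit <- classifySequence(rcStr(substr(l1, 1, 500)), lib)
  expect_equal(revhit$family, "L1")
  expect_equal(revhit$orientation, "-")

  div <- withr::with_seed(9, retrofind:::mutateSeqs(l1, 0.10))
  dh <- classifySequence(div, lib)
  expect_equal(dh$family, "L1")
  expect_lt(abs(dh$identityPct - 90), 3)
})

test_that("classification is orientation-symmetric", {
  lib <- fixtureLibrary()
  sva <- as.character(consensusSeqs(lib)[["SVA_E"]])
  seq <- withr::with_seed(3, retrofind:::mutateSeqs(sva, 0.05))
  fwd <- classifySequence(seq, lib)
  rev <- classifySequence(rcStr(seq), lib)
  expect_equal(fwd$family, rev$family)
  expect_equal(fwd$identityPct, rev$identityPct, tolerance = 1e-6)
  expect_true(fwd$orientation != rev$orientation)
})

test_that("sequences shorter than 30 bp are refused", {
  expect_error(classifySequence("ACGTACGT", fixtureLibrary()),
               "shorter than 30")
})
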