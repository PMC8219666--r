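## Independent oracles and shared fixtures.

## Plain-R Smith-Waterman with affine gaps, scoring match +2 / mismatch
## -4 / gap open -4 / gap extend -2 (opening a gap of length 1 costs
## open + extend = -6, matching pairwiseAlignment's convention). Used as
## the independent check of the alignment contract.
swOracleScore <- function(query, target) {
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  t <- strsplit(target, "", fixed = TRUE)[[1L]]
  n <- length(q); m <- length(t)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)       # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)     # gap in target (query consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)     # gap in query
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (q[i - 1L] == t[j - 1L]) 2 else -4
      M[i, j] <- max(0, M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - 6, X[i - 1L, j] - 2)
      Y[i, j] <- max(M[i, j - 1L] - 6, Y[i, j - 1L] - 2)
      best <- max(best, M[i, j])
    }
  }
  best
}

## Best local score over both orientations, as alignPair reports.
swOracleBoth <- function(query, target) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  max(swOracleScore(query, target), swOracleScore(rc, target))
}

## Allele-transmission enumeration for trio consistency.
mendelianOracle <- function(f, m, c) {
  alleles <- function(g) if (g == 1L) c(0L, 1L) else rep(g %/% 2L, 1L)
  c %in% unique(as.vector(outer(alleles(f), alleles(m), "+")))
}

## Random DNA under the current RNG.
rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")

rcStr <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

## ---- shared fixtures, built once per session ------------------------

.fixtureCache <- new.env(parent = emptyenv())

fixtureCached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## small mixed-event short-read scenario used by several unit tests
fixtureShortMini <- function() fixtureCached("shortMini", function() {
  cfg <- simConfig(seed = 11L, genomeLength = 400000L,
                   events = data.frame(
                     type = c("alu", "l1_trunc", "transduction_canonical",
                              "transduction_orphan", "target_site_deletion"),
                     count = c(3L, 2L, 1L, 1L, 1L)))
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateShortReads(ref, planted)
  genome <- Biostrings::DNAStringSet(ref$seq)
  names(genome) <- ref$chrom
  list(ref = ref, planted = planted, tbl = tbl, genome = genome)
})

fixtureShortMiniCalls <- function() fixtureCached("shortMiniCalls", function() {
  fx <- fixtureShortMini()
  stats <- estimateLibraryStats(fx$tbl)
  calls <- callInsertionsShort(fx$tbl, fx$genome, fx$ref$library,
                               fx$ref$rmsk, stats = stats)
  list(calls = calls, stats = stats)
})

## small long-read scenario
fixtureLongMini <- function() fixtureCached("longMini", function() {
  cfg <- simConfig(seed = 12L, genomeLength = 400000L,
                   events = data.frame(type = c("alu", "l1_trunc"),
                                       count = c(2L, 1L)))
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateLongReads(ref, planted)
  genome <- Biostrings::DNAStringSet(ref$seq)
  names(genome) <- ref$chrom
  list(ref = ref, planted = planted, tbl = tbl, genome = genome)
})

## full-size study scenarios shared between module tests and the
## end-to-end acceptance tests
fixtureScenarioA <- function() fixtureCached("scenarioA", function() {
  sc <- simulateScenarioShort(seed = 1L)
  genome <- Biostrings::DNAStringSet(sc$ref$seq)
  names(genome) <- sc$ref$chrom
  stats <- estimateLibraryStats(sc$tbl)
  calls <- callInsertionsShort(sc$tbl, genome, sc$ref$library,
                               sc$ref$rmsk, stats = stats)
  c(sc, list(genome = genome, stats = stats, calls = calls))
})

fixtureScenarioB <- function() fixtureCached("scenarioB", function() {
  sc <- simulateScenarioLong(seed = 1L)
  genome <- Biostrings::DNAStringSet(sc$ref$seq)
  names(genome) <- sc$ref$chrom
  calls <- callInsertionsLong(sc$tbl, genome, sc$ref$library)
  c(sc, list(genome = genome, calls = calls))
})

## a minimal consensus library fixture
fixtureLibrary <- function() fixtureCached("library", miniConsensusLibrary)

## quick constructor for small hand-made alignment tables
mkAlnTable <- function(pos, cigar, seq = NA_character_, flag = 99L,
                       chrom = "chr1", mapq = 60L, qname = NULL,
                       mpos = 0L, tlen = 0L) {
  n <- max(length(pos), length(cigar))
  alignmentTable(data.frame(
    qname = if (is.null(qname)) sprintf("r%03d", seq_len(n)) else qname,
    flag = rep_len(flag, n), chrom = rep_len(chrom, n),
    pos = rep_len(pos, n), mapq = rep_len(mapq, n),
    cigar = rep_len(cigar, n), mchrom = rep_len(chrom, n),
    mpos = rep_len(mpos, n), tlen = rep_len(tlen, n),
    seq = rep_len(seq, n)))
}

## 25 constructed L1 contigs, 5 per structural category
l1StructureCases <- function() {
  lib <- fixtureLibrary()
  cons <- as.character(consensusSeqs(lib)[["L1HS"]])
  n <- nchar(cons)
  pA <- strrep("A", 25)
  sub <- function(a, b) substr(cons, a, b)
  cases <- list()
  add <- function(cat, seq) {
    cases[[length(cases) + 1L]] <<- list(category = cat, seq = seq)
  }
  withr::with_seed(30, {
    ## full length (one with light divergence)
    for (k in 1:5) {
      s <- if (k <= 2) cons else retrofind:::mutateSeqs(cons, 0.01)
      add("full_length", paste0(s, pA))
    }
    ## 5' truncated
    for (tp in c(1500, 2500, 3000, 4000, 4500))
      add("truncated_5p", paste0(sub(tp + 1, n), pA))
    ## internal deletion (gaps 25..500)
    for (gap in c(25, 60, 120, 250, 500))
      add("internal_deletion", paste0(sub(1, 3000), sub(3001 + gap, n), pA))
    ## internal inversion (twin priming, contiguous on the consensus)
    for (j in c(2500, 3000, 3500, 4000, 4500))
      add("internal_inversion",
          paste0(rcStr(sub(j - 1500, j)), sub(j + 1, n), pA))
    ## deletion and inversion
    for (gap in c(30, 80, 150, 300, 450))
      add("deletion_and_inversion",
          paste0(rcStr(sub(2000, 3200)), sub(3201 + gap, n), pA))
  })
  cases
}

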