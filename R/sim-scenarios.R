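## Canned simulation scenarios: the study conditions under which the
## caller, genotyper and annotators are validated end to end. Problem
## sizes are chosen so a full scenario runs in minutes on one CPU; the
## methods vignette discusses the choices.

#' Short-read end-to-end scenario
#'
#' 2 Mb genome, 30 planted events (Alu, full/truncated/inverted/
#' internally deleted L1, SVA, canonical and orphan transductions) at
#' 30X, 150 bp reads, 500 +/- 50 bp inserts, 0.2\% error.
#'
#' @param seed Master seed.
#' @param genomeLength Override the genome size.
#' @return list(ref, planted, tbl) with the alignment table in \code{tbl}.
#' @export
simulateScenarioShort <- function(seed = 1L, genomeLength = 2000000L) {
  events <- data.frame(
    type = c("alu", "l1_full", "l1_trunc", "l1_inv", "l1_del", "sva",
             "transduction_canonical", "transduction_orphan"),
    count = c(12L, 4L, 5L, 2L, 1L, 3L, 2L, 1L))
  cfg <- simConfig(seed = seed, genomeLength = genomeLength,
                   events = events)
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateShortReads(ref, planted)
  list(ref = ref, planted = planted, tbl = tbl)
}

#' Long-read end-to-end scenario
#'
#' 1 Mb genome, 20 planted events at 20X long reads (12 +/- 2 kb), 1\%
#' error.
#'
#' @param seed Master seed.
#' @return list(ref, planted, tbl).
#' @export
simulateScenarioLong <- function(seed = 1L) {
  events <- data.frame(
    type = c("alu", "l1_full", "l1_trunc", "l1_inv", "sva",
             "transduction_canonical"),
    count = c(8L, 3L, 4L, 2L, 2L, 1L))
  cfg <- simConfig(seed = seed, genomeLength = 1000000L, events = events)
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateLongReads(ref, planted)
  list(ref = ref, planted = planted, tbl = tbl)
}

#' Matched tumor/normal somatic scenario
#'
#' 10 somatic (tumor-only) plus 10 germline Alu/L1 events on a 900 kb
#' genome; tumor at 60X, normal at 30X, error-free reads.
#'
#' @param seed Master seed.
#' @return list(ref, tumorTbl, normalTbl, truthTumor, truthNormal).
#' @export
simulateScenarioSomatic <- function(seed = 1L) {
  cfg <- simConfig(seed = seed, genomeLength = 900000L,
                   shortRead = list(depth = 60, readLen = 150L,
                                    meanInsert = 500, sdInsert = 50,
                                    errorRate = 0))
  ref <- simulateReference(cfg)
  germline <- data.frame(type = c("alu", "l1_trunc"), count = c(6L, 4L),
                         zygosity = "het")
  somatic <- data.frame(type = c("alu", "l1_trunc"), count = c(6L, 4L),
                        zygosity = "het")
  plantedNormal <- plantInsertions(ref, germline, seed = cfg$seed + 11L)
  ## tumor carries the germline events plus somatic ones; rebuild from the
  ## union so positions do not collide
  both <- rbind(cbind(germline, origin = "germline"),
                cbind(somatic, origin = "somatic"))
  plantedTumor <- plantInsertions(ref, both, seed = cfg$seed + 11L)
  ## identify somatic truth rows: those not at germline positions
  germPos <- plantedNormal$truth$pos
  plantedTumor$truth$somatic <- !(plantedTumor$truth$pos %in% germPos)
  normalTbl <- simulateShortReads(ref, plantedNormal,
                                  seed = cfg$seed + 12L, depth = 30)
  tumorTbl <- simulateShortReads(ref, plantedTumor,
                                 seed = cfg$seed + 13L, depth = 60)
  list(ref = ref, tumorTbl = tumorTbl, normalTbl = normalTbl,
       truthTumor = plantedTumor$truth, truthNormal = plantedNormal$truth)
}

#' Ghost-L1 scenario
#'
#' k full-length L1 copies planted inside centromeric satellite blocks,
#' observed through donor-mapped both-side-clipped long reads.
#'
#' @param seed Master seed.
#' @param k Number of planted ghost copies (1-3).
#' @return list(ref, planted, tbl).
#' @export
simulateScenarioGhost <- function(seed = 1L, k = 2L) {
  ## ghost evidence comes from the dedicated donor-mapped reads, so the
  ## ordinary long-read depth is kept minimal
  cfg <- simConfig(seed = seed, genomeLength = 600000L,
                   nFullL1 = 2L,
                   events = data.frame(type = "ghost_l1", count = k,
                                       zygosity = "het"),
                   longRead = list(depth = 4, meanLen = 12000L,
                                   sdLen = 2000L, minLen = 3000L,
                                   errorRate = 0.01, ghostReads = 6L))
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateLongReads(ref, planted)
  list(ref = ref, planted = planted, tbl = tbl)
}

#' Dimorphic-HERV scenario
#'
#' A proviral HERV (optionally with an internal deletion) planted at one
#' solo-LTR locus and a negative control (Alu middle) at the other.
#'
#' @param seed Master seed.
#' @param internalDeletion Internal deletion length in bp (0 = none).
#' @param withNegative Plant the negative control too.
#' @return list(ref, planted, tbl).
#' @export
simulateScenarioHerv <- function(seed = 1L, internalDeletion = 0L,
                                 withNegative = TRUE) {
  events <- data.frame(type = "herv_provirus", count = 1L,
                       zygosity = "hom", param = internalDeletion,
                       locus = 1L)
  if (withNegative)
    events <- rbind(events,
                    data.frame(type = "herv_negative", count = 1L,
                               zygosity = "hom", param = NA, locus = 2L))
  cfg <- simConfig(seed = seed, genomeLength = 400000L, events = events)
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateLongReads(ref, planted)
  list(ref = ref, planted = planted, tbl = tbl)
}

#' TE-mediated SV scenario
#'
#' One Alu-driven deletion, duplication and inversion each, observed
#' through split long reads.
#'
#' @param seed Master seed.
#' @return list(ref, planted, tbl).
#' @export
simulateScenarioSv <- function(seed = 1L) {
  events <- data.frame(type = c("sv_deletion", "sv_duplication",
                                "sv_inversion"),
                       count = 1L, zygosity = "hom",
                       param = c(5000L, 2000L, 1000L))
  cfg <- simConfig(seed = seed, genomeLength = 700000L, events = events)
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateLongReads(ref, planted)
  list(ref = ref, planted = planted, tbl = tbl)
}

#' Pseudogene scenario
#'
#' One processed-pseudogene insertion (concatenated exons + polyA) on a
#' small genome with two annotated genes, observed with long reads.
#'
#' @param seed Master seed.
#' @return list(ref, planted, tbl, exonIndex).
#' @export
simulateScenarioPseudogene <- function(seed = 1L) {
  cfg <- simConfig(seed = seed, genomeLength = 400000L,
                   events = data.frame(type = "pseudogene", count = 1L,
                                       zygosity = "hom"))
  ref <- simulateReference(cfg)
  planted <- plantInsertions(ref)
  tbl <- simulateLongReads(ref, planted)
  bed <- tempfile(fileext = ".bed")
  writeExonsBed(ref$transcripts, bed)
  g <- DNAStringSet(ref$seq); names(g) <- ref$chrom
  exonIndex <- readExonsBed(bed, g)
  unlink(bed)
  list(ref = ref, planted = planted, tbl = tbl, exonIndex = exonIndex)
}

#' Match calls against simulator truth
#'
#' @param callset An \code{\link{InsertionCallSet}}.
#' @param truth Truth events.
#' @param tolerance Breakpoint tolerance in bp (default 25).
#' @return list(recall, precision, nMatched, breakpointErrors (bp, one
#'   per matched truth event), matchedIdx).
#' @export
scoreAgainstTruth <- function(callset, truth, tolerance = 25L) {
  gr <- insertionCalls(callset)
  callPos <- start(gr)
  errs <- integer(0); matched <- logical(nrow(truth))
  usedCall <- logical(length(gr))
  for (i in seq_len(nrow(truth))) {
    d <- abs(callPos - truth$pos[i])
    d[usedCall] <- Inf
    if (length(d) && min(d) <= tolerance) {
      j <- which.min(d)
      usedCall[j] <- TRUE
      matched[i] <- TRUE
      errs <- c(errs, as.integer(min(d)))
    }
  }
  list(recall = if (nrow(truth)) mean(matched) else NA_real_,
       precision = if (length(gr)) mean(usedCall) else NA_real_,
       nMatched = sum(matched), breakpointErrors = errs,
       matchedIdx = which(matched))
}
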