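## Planting insertion events into haplotypes.
##
## An event is anchored at pos (the last reference base before the
## junction). The haplotype is reference[1..pos] + insSeq + reference
## resuming at nextStart: nextStart = pos - tsdLen + 1 realizes a
## target-site duplication, nextStart = pos + span + 1 a target-site /
## SV deletion, and nextStart = pos - span + 1 an SV duplication.

.eventTypes <- c("alu", "sva", "l1_full", "l1_trunc", "l1_inv", "l1_del",
                 "transduction_canonical", "transduction_orphan",
                 "pseudogene", "herv_provirus", "herv_negative",
                 "ghost_l1", "target_site_deletion", "sv_deletion",
                 "sv_duplication", "sv_inversion")

.emptyTruth <- function() {
  data.frame(id = integer(0), type = character(0), chrom = character(0),
             pos = integer(0), zygosity = character(0),
             family = character(0), subfamily = character(0),
             tsdLen = integer(0), polyALen = integer(0),
             insLen = integer(0), insSeq = character(0),
             nextStart = integer(0), srcStart = integer(0),
             srcEnd = integer(0), donorIdx = integer(0),
             gene = character(0), spanStart = integer(0),
             spanEnd = integer(0))
}

#' Plant insertion events into two haplotypes
#'
#' Events are placed in nonrepetitive background sequence (except ghost
#' L1s, which go inside satellite blocks, and proviral HERVs, which sit
#' at solo-LTR loci) with a minimum spacing of 10 kb. TSDs of 5-20 bp and
#' polyA tails of 10-40 bp are added where mechanistically appropriate;
#' transductions copy the flank window of a planted full-length source.
#'
#' @param ref From \code{\link{simulateReference}}.
#' @param events data.frame(type, count) with optional columns
#'   \code{zygosity} ("het"/"hom"), \code{param} (type-specific: the
#'   internal-deletion length for herv_provirus, span for SV types).
#' @param seed Seed (defaults to config seed + 1).
#' @param minSpacing Minimum distance between events (default 10 kb).
#' @return list(truth = data.frame of truth events, hap1, hap2) where
#'   each haplotype is list(pieces, seq) from
#'   \code{\link{buildHaplotype}}.
#' @export
plantInsertions <- function(ref, events = ref$config$events,
                            seed = ref$config$seed + 1L,
                            minSpacing = 10000L) {
  recs <- consensusSeqs(ref$library)
  G <- nchar(ref$seq)
  withSeed(seed, {
    ## forbidden intervals for ordinary placement; satellite blocks get a
    ## wide margin so reads crossing an event never run into excluded
    ## (unmappable) sequence
    occ <- cbind(start(ref$rmsk) - 1500L, end(ref$rmsk) + 1500L)
    occ <- rbind(occ, cbind(ref$transcripts$txStart - 500L,
                            ref$transcripts$txEnd + 500L))
    if (length(ref$satBlocks))
      occ <- rbind(occ, cbind(start(ref$satBlocks) - 16000L,
                              end(ref$satBlocks) + 16000L))
    placedPos <- integer(0)
    placeBg <- function(spanExtra = 0L) {
      for (try in 1:5000) {
        p <- sample.int(G - 30000L - spanExtra, 1L) + 10000L
        if (any(p <= occ[, 2] & p + spanExtra >= occ[, 1])) next
        if (length(placedPos) && min(abs(placedPos - p)) < minSpacing) next
        placedPos <<- c(placedPos, p)
        return(p)
      }
      stop("could not place event: genome too crowded")
    }
    rows <- list()
    evId <- 0L
    satCycle <- 0L
    addEvent <- function(type, pos, insSeq, zyg, tsdLen = 0L,
                         polyALen = 0L, nextStart = pos - tsdLen + 1L,
                         family = NA, subfamily = NA, srcStart = NA,
                         srcEnd = NA, donorIdx = NA, gene = NA,
                         spanStart = NA, spanEnd = NA) {
      evId <<- evId + 1L
      rows[[evId]] <<- data.frame(
        id = evId, type = type, chrom = ref$chrom, pos = pos,
        zygosity = zyg, family = as.character(family),
        subfamily = as.character(subfamily), tsdLen = tsdLen,
        polyALen = polyALen, insLen = nchar(insSeq), insSeq = insSeq,
        nextStart = as.integer(nextStart),
        srcStart = as.integer(srcStart), srcEnd = as.integer(srcEnd),
        donorIdx = as.integer(donorIdx), gene = as.character(gene),
        spanStart = as.integer(spanStart), spanEnd = as.integer(spanEnd))
    }
    pA <- function(n) strrep("A", n)
    for (r in seq_len(nrow(events))) {
      type <- events$type[r]
      stopifnot(type %in% .eventTypes)
      cnt <- events$count[r]
      for (k in seq_len(cnt)) {
        zyg <- if ("zygosity" %in% names(events) && !is.na(events$zygosity[r]))
          events$zygosity[r] else sample(c("het", "hom"), 1L)
        param <- if ("param" %in% names(events)) events$param[r] else NA
        tsd <- sample(5:20, 1L)
        pal <- sample(10:40, 1L)
        if (type == "alu" || type == "sva") {
          subf <- if (type == "alu") sample(c("AluYa5", "AluYb8"), 1L)
                  else "SVA_E"
          ins <- paste0(mutateSeqs(as.character(recs[[subf]]), 0.005),
                        pA(pal))
          addEvent(type, placeBg(), ins, zyg, tsd, pal,
                   family = familyOf(ref$library, subf), subfamily = subf)
        } else if (type == "l1_full") {
          ins <- paste0(mutateSeqs(as.character(recs[["L1HS"]]), 0.005),
                        pA(pal))
          addEvent(type, placeBg(), ins, zyg, tsd, pal,
                   family = "L1", subfamily = "L1HS")
        } else if (type == "l1_trunc") {
          tp <- sample(2000:4500, 1L)
          cons <- as.character(recs[["L1HS"]])
          ins <- paste0(mutateSeqs(substr(cons, tp + 1L, nchar(cons)), 0.005),
                        pA(pal))
          addEvent(type, placeBg(), ins, zyg, tsd, pal,
                   family = "L1", subfamily = "L1HS")
        } else if (type == "l1_inv") {
          cons <- as.character(recs[["L1HS"]])
          ins <- paste0(revComp(substr(cons, 3001L, 4500L)),
                        substr(cons, 4501L, 6000L), pA(pal))
          addEvent(type, placeBg(), mutateSeqs(ins, 0.003), zyg, tsd, pal,
                   family = "L1", subfamily = "L1HS")
        } else if (type == "l1_del") {
          gap <- sample(50:200, 1L)
          cons <- as.character(recs[["L1HS"]])
          ins <- paste0(substr(cons, 2000L, 3500L),
                        substr(cons, 3501L + gap, 6000L), pA(pal))
          addEvent(type, placeBg(), mutateSeqs(ins, 0.003), zyg, tsd, pal,
                   family = "L1", subfamily = "L1HS")
        } else if (type %in% c("transduction_canonical",
                               "transduction_orphan")) {
          w <- sample(length(flankIndex(ref$library)), 1L)
          tdLen <- sample(400:800, 1L)
          tdSeq <- substr(as.character(flankSeqs(ref$library)[[w]]), 1L, tdLen)
          cons <- as.character(recs[["L1HS"]])
          ins <- if (type == "transduction_canonical")
            paste0(substr(cons, 3001L, 6000L), pA(15L), tdSeq, pA(pal))
          else paste0(tdSeq, pA(pal))
          fi <- flankIndex(ref$library)[w]
          addEvent(type, placeBg(), ins, zyg, tsd, pal,
                   family = "L1", subfamily = "L1HS",
                   srcStart = start(fi), srcEnd = end(fi))
        } else if (type == "pseudogene") {
          gi <- sample(nrow(ref$transcripts), 1L)
          es <- ref$transcripts$exonStarts[[gi]]
          ee <- ref$transcripts$exonEnds[[gi]]
          exons <- substring(ref$seq, es, ee)
          ins <- paste0(paste(exons, collapse = ""), pA(25L))
          addEvent(type, placeBg(), ins, zyg, tsd, 25L,
                   family = "pseudogene", gene = ref$transcripts$gene[gi])
        } else if (type %in% c("herv_provirus", "herv_negative")) {
          li <- if ("locus" %in% names(events)) events$locus[r] else k
          li <- min(li, length(ref$soloLtrs))
          locus <- ref$soloLtrs[li]
          pos <- end(locus)
          ltrSeq <- substring(ref$seq, start(locus), end(locus))
          if (type == "herv_provirus") {
            internal <- mutateSeqs(as.character(recs[["HERVK_int"]]), 0.005)
            d <- if (!is.na(param)) as.integer(param) else 0L
            if (d > 0L) {
              L <- nchar(internal)
              a <- as.integer(floor((L - d) / 2))
              internal <- paste0(substr(internal, 1L, a),
                                 substr(internal, a + d + 1L, L))
            }
            ins <- paste0(internal, ltrSeq)
          } else {
            ins <- paste0(mutateSeqs(as.character(recs[["AluYa5"]]), 0.005),
                          ltrSeq)
          }
          placedPos <- c(placedPos, pos)
          addEvent(type, pos, ins, zyg, 0L, 0L, nextStart = pos + 1L,
                   family = "HERV", subfamily = "HERVK_int",
                   donorIdx = li)
        } else if (type == "ghost_l1") {
          satCycle <- satCycle + 1L
          sb <- ref$satBlocks[((satCycle - 1L) %% length(ref$satBlocks)) + 1L]
          pos <- sample((start(sb) + 2500L):(end(sb) - 2500L), 1L)
          placedPos <- c(placedPos, pos)
          donor <- sample(length(ref$fullL1s), 1L)
          ins <- paste0(mutateSeqs(as.character(recs[["L1HS"]]), 0.005),
                        pA(20L))
          addEvent(type, pos, ins, zyg, 0L, 20L, nextStart = pos + 1L,
                   family = "L1", subfamily = "L1HS", donorIdx = donor)
        } else if (type == "target_site_deletion") {
          span <- sample(600:1000, 1L)
          ins <- paste0(mutateSeqs(as.character(recs[["AluYa5"]]), 0.005),
                        pA(pal))
          pos <- placeBg(span)
          addEvent(type, pos, ins, zyg, 0L, pal, nextStart = pos + span + 1L,
                   family = "Alu", subfamily = "AluYa5",
                   spanStart = pos + 1L, spanEnd = pos + span)
        } else if (type == "sv_deletion") {
          span <- if (!is.na(param)) as.integer(param) else 5000L
          ins <- mutateSeqs(as.character(recs[["AluYa5"]]), 0.005)
          pos <- placeBg(span)
          addEvent(type, pos, ins, zyg, 0L, 0L, nextStart = pos + span + 1L,
                   family = "Alu", subfamily = "AluYa5",
                   spanStart = pos + 1L, spanEnd = pos + span)
        } else if (type == "sv_duplication") {
          span <- if (!is.na(param)) as.integer(param) else 2000L
          ins <- mutateSeqs(as.character(recs[["AluYa5"]]), 0.005)
          pos <- placeBg(span)
          addEvent(type, pos, ins, zyg, 0L, 0L, nextStart = pos - span + 1L,
                   family = "Alu", subfamily = "AluYa5",
                   spanStart = pos - span + 1L, spanEnd = pos)
        } else if (type == "sv_inversion") {
          span <- if (!is.na(param)) as.integer(param) else 1000L
          pos <- placeBg(span)
          ins <- paste0(mutateSeqs(as.character(recs[["AluYa5"]]), 0.005),
                        revComp(substring(ref$seq, pos + 1L, pos + span)))
          addEvent(type, pos, ins, zyg, 0L, 0L, nextStart = pos + span + 1L,
                   family = "Alu", subfamily = "AluYa5",
                   spanStart = pos + 1L, spanEnd = pos + span)
        }
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else .emptyTruth()
    truth <- truth[order(truth$pos), , drop = FALSE]
    truth$id <- seq_len(nrow(truth))
    rownames(truth) <- NULL
    hap1 <- buildHaplotype(ref$seq, truth)                     # carries all
    hap2 <- buildHaplotype(ref$seq,
                           truth[truth$zygosity == "hom", , drop = FALSE])
    list(truth = truth, hap1 = hap1, hap2 = hap2)
  })
}

#' Build a haplotype from planted events
#'
#' @param refSeq Reference sequence (character).
#' @param truth Truth events (sorted by \code{pos}) carried by this
#'   haplotype.
#' @return list(pieces, seq): \code{pieces} has one row per alternating
#'   reference / insertion piece with haplotype and reference
#'   coordinates; \code{seq} is the haplotype sequence.
#' @export
buildHaplotype <- function(refSeq, truth) {
  G <- nchar(refSeq)
  pieces <- list(); parts <- list()
  cur <- 1L; hap <- 0L
  addPiece <- function(type, refStart, refEnd, seq, eventId) {
    n <- nchar(seq)
    pieces[[length(pieces) + 1L]] <<- data.frame(
      type = type, hapStart = hap + 1L, hapEnd = hap + n,
      refStart = refStart, refEnd = refEnd, eventId = eventId)
    parts[[length(parts) + 1L]] <<- seq
    hap <<- hap + n
  }
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      ev <- truth[i, ]
      if (ev$pos >= cur)
        addPiece("ref", cur, ev$pos, substr(refSeq, cur, ev$pos), NA)
      addPiece("ins", NA, NA, ev$insSeq, ev$id)
      cur <- ev$nextStart
    }
  }
  if (cur <= G) addPiece("ref", cur, G, substr(refSeq, cur, G), NA)
  list(pieces = do.call(rbind, pieces), seq = paste(unlist(parts),
                                                    collapse = ""))
}
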