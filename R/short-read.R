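## Germline TE-insertion discovery from Illumina paired-end alignments.
##
## Discovery is clip-first: candidate sites are positions where soft-clipped
## read ends stack, and every candidate is then profiled on the TE consensus.
## Clips of right-clipped reads (the 5' genomic side of the insertion) form
## cluster c1, clips of left-clipped reads form c2; mates of discordant
## reads anchored on the 5' side form d2, on the 3' side d1. A two-sided
## candidate passes when each category concentrates in a single cluster and
## |c1-d2| and |c2-d1| are below the insert-size gate mu + 3*sigma.
## One-sided candidates are routed to transduction tracing or target-site
## deletion resolution instead of being rejected.

#' Collect clip-stack candidate sites
#'
#' Positions where soft/hard-clipped read ends (clip length >= 10 bp)
#' stack within +/- 3 bp with total clip support above the threshold.
#' Duplicate and MAPQ-0 records are excluded. The two clip sides are
#' merged into one candidate when their anchors are within 50 bp (the
#' target-site-duplication scale).
#'
#' @param tbl Coordinate-sorted alignment table.
#' @param thresholds From \code{\link{autoThresholds}}.
#' @param minClipLen Minimum clip length considered (default 10).
#' @param clusterWindow Clip-stack window (default 3 bp).
#' @param sideMergeWindow Window for pairing the two clip sides (default 50).
#' @return A list of candidate sites; each has \code{chrom}, \code{site}
#'   (1-based insertion anchor), \code{anchorR}/\code{anchorL} (modal
#'   anchors of right-/left-clipped reads, NA when absent), counts,
#'   per-side clipped sequences, and member read names.
#' @export
collectClipCandidates <- function(tbl, thresholds, minClipLen = 10L,
                                  clusterWindow = 3L, sideMergeWindow = 50L) {
  checkSorted(tbl)
  use <- tbl$isMapped & !tbl$isDup & tbl$mapq > 0L & !tbl$isSupp
  recR <- which(use & tbl$clipR >= minClipLen)
  recL <- which(use & tbl$clipL >= minClipLen)
  clips <- data.frame(
    row = c(recR, recL),
    side = rep(c("R", "L"), c(length(recR), length(recL))),
    chrom = tbl$chrom[c(recR, recL)],
    anchor = c(tbl$endpos[recR], tbl$pos[recL] - 1L))
  if (!nrow(clips)) return(list())
  out <- list()
  for (chrom in unique(clips$chrom)) {
    cc <- clips[clips$chrom == chrom, ]
    sideClusters <- list()
    for (sd in c("R", "L")) {
      cs <- cc[cc$side == sd, ]
      if (!nrow(cs)) next
      cid <- gapCluster(cs$anchor, clusterWindow)
      for (k in unique(cid)) {
        rows <- cs$row[cid == k]
        anchors <- cs$anchor[cid == k]
        sideClusters[[length(sideClusters) + 1L]] <- list(
          side = sd, anchor = modalValue(anchors), n = length(rows),
          rows = rows)
      }
    }
    if (!length(sideClusters)) next
    sides <- vapply(sideClusters, `[[`, "", "side")
    anchors <- vapply(sideClusters, function(x) x$anchor, 0L)
    iR <- which(sides == "R"); iL <- which(sides == "L")
    usedL <- logical(length(iL))
    pairup <- function(r, l) {
      rowsR <- if (!is.na(r)) sideClusters[[r]]$rows else integer(0)
      rowsL <- if (!is.na(l)) sideClusters[[l]]$rows else integer(0)
      aR <- if (!is.na(r)) sideClusters[[r]]$anchor else NA_integer_
      aL <- if (!is.na(l)) sideClusters[[l]]$anchor else NA_integer_
      seqsR <- vapply(rowsR, function(i)
        clipSeq(tbl$seq[i], tbl$clipL[i], tbl$clipR[i], "right"), "")
      seqsL <- vapply(rowsL, function(i)
        clipSeq(tbl$seq[i], tbl$clipL[i], tbl$clipR[i], "left"), "")
      list(chrom = chrom,
           site = if (!is.na(aR)) aR else aL,
           anchorR = aR, anchorL = aL,
           countR = length(rowsR), countL = length(rowsL),
           seqsR = seqsR[!is.na(seqsR)], seqsL = seqsL[!is.na(seqsL)],
           qnames = unique(tbl$qname[c(rowsR, rowsL)]))
    }
    for (r in iR) {
      d <- abs(anchors[iL] - anchors[r])
      j <- if (length(iL)) which(!usedL & d <= sideMergeWindow) else integer(0)
      if (length(j)) {
        j <- j[which.min(d[j])]
        usedL[j] <- TRUE
        out[[length(out) + 1L]] <- pairup(r, iL[j])
      } else out[[length(out) + 1L]] <- pairup(r, NA)
    }
    for (j in seq_along(iL))
      if (!usedL[j]) out[[length(out) + 1L]] <- pairup(NA, iL[j])
  }
  keep <- vapply(out, function(x)
    (x$countR + x$countL) >= thresholds$minClipReads, TRUE)
  out[keep]
}

## Sequences of mates of discordant reads anchored near a site, split by
## the side of the anchored read. mateSeqIndex is a named character vector
## qname -> sequence of the unanchored (unmapped / distant) mate.
discordantMates <- function(tbl, chrom, site, window, mateSeqIndex) {
  sel <- tbl$isMapped & !tbl$isSupp & !tbl$isDup & tbl$chrom == chrom &
    !tbl$isProper & tbl$pos >= site - window & tbl$pos <= site + window
  if (!any(sel)) return(list(left = character(0), right = character(0),
                             n = 0L))
  qn <- tbl$qname[sel]
  mseq <- mateSeqIndex[qn]
  mid <- (tbl$pos[sel] + tbl$endpos[sel]) / 2
  ok <- !is.na(mseq)
  list(left = unname(mseq[ok & mid <= site]),
       right = unname(mseq[ok & mid > site]),
       n = sum(sel))
}

## Index of mate sequences for discordant evidence: sequence of every
## unmapped record keyed by read name.
mateSeqIndex <- function(tbl) {
  un <- !tbl$isMapped & !is.na(tbl$seq) & tbl$seq != "*" & tbl$seq != ""
  structure(tbl$seq[un], names = tbl$qname[un])
}

## One alignment category mapped onto a consensus: largest single-linkage
## cluster (50 bp) of hit centers.
.clusterCategory <- function(hits, gap = 50L) {
  if (!nrow(hits)) return(NULL)
  centers <- (hits$tstart + hits$tend) / 2
  cid <- gapCluster(as.integer(centers), gap)
  sizes <- table(cid)
  k <- as.integer(names(sizes)[which.max(sizes)])
  inC <- cid == k
  list(center = mean(centers[inC]),
       span = max(centers[inC]) - min(centers[inC]),
       size = sum(inC), total = nrow(hits))
}

#' Map a candidate's supporting sequences onto the TE consensus
#'
#' Every clipped sequence and discordant mate is aligned to every library
#' record; the subfamily with the most accepted hits wins, and the four
#' evidence categories (c1 = 5'-side clips, c2 = 3'-side clips, d1 = mates
#' of 3'-side discordant reads, d2 = mates of 5'-side discordant reads)
#' are clustered on the consensus coordinate (single linkage, 50 bp).
#'
#' @param candidate One element of \code{\link{collectClipCandidates}}.
#' @param discLeft,discRight Mate sequences by anchored-read side.
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param minHitLen,minHitIdentity,minHitScore Hit acceptance (default
#'   25 bp, 80, score 40): tight enough that random genomic sequence
#'   (e.g. a transduced flank) does not pass.
#' @param maxPerCategory Evidence cap per category (default 24).
#' @param excludeFamilies Library families never profiled against
#'   (satellite classes by default).
#' @return A consensus profile: \code{subfamily}, \code{family},
#'   clusters \code{c1}/\code{c2}/\code{d1}/\code{d2} (NULL when the
#'   category has no accepted hits), \code{orientation}, and
#'   \code{nAligned}/\code{nTotal} sequence counts. A candidate none of
#'   whose sequences align yields a profile with all clusters NULL.
#' @export
buildConsensusProfile <- function(candidate, discLeft = character(0),
                                  discRight = character(0), library,
                                  minHitLen = 25L, minHitIdentity = 80,
                                  minHitScore = 40, maxPerCategory = 24L,
                                  excludeFamilies = c("Alpha", "Beta",
                                                      "HSATII")) {
  cats <- list(c1 = candidate$seqsR, c2 = candidate$seqsL,
               d1 = discRight, d2 = discLeft)
  cats <- lapply(cats, function(x) {
    x <- x[!is.na(x) & nchar(x) >= minHitLen]
    if (length(x) > maxPerCategory) x[seq_len(maxPerCategory)] else x
  })
  catId <- rep(names(cats), lengths(cats))
  seqs <- unlist(cats, use.names = FALSE)
  empty <- list(subfamily = NA_character_, family = NA_character_,
                c1 = NULL, c2 = NULL, d1 = NULL, d2 = NULL,
                orientation = NA_character_,
                nAligned = 0L, nTotal = length(seqs))
  if (!length(seqs)) return(empty)
  recs <- consensusSeqs(library)
  fams <- familyOf(library, names(recs))
  recs <- recs[!fams %in% excludeFamilies]
  accept <- function(h) (h$tend - h$tstart + 1L) >= minHitLen &
    h$identity >= minHitIdentity & h$score >= minHitScore
  ## prescreen with a few sequences per category to pick the subfamily,
  ## then profile all evidence against the winner only
  preIdx <- unlist(lapply(unique(catId), function(cat) {
    which(catId == cat)[seq_len(min(6L, sum(catId == cat)))]
  }))
  pre <- seqs[preIdx]
  nAcc <- numeric(length(recs)); sAcc <- numeric(length(recs))
  for (i in seq_along(recs)) {
    h <- alignBatch(pre, recs[[i]])
    ok <- accept(h)
    nAcc[i] <- sum(ok)
    sAcc[i] <- sum(h$score[ok])
  }
  if (max(nAcc) == 0) return(empty)
  win <- order(-nAcc, -sAcc)[1L]
  best <- list(subfamily = names(recs)[win])
  h <- alignBatch(seqs, recs[[win]])
  h$accepted <- accept(h)
  best$n <- sum(h$accepted)
  if (best$n == 0L) return(empty)
  clusters <- lapply(c("c1", "c2", "d1", "d2"), function(cat) {
    .clusterCategory(h[h$accepted & catId == cat, , drop = FALSE])
  })
  names(clusters) <- c("c1", "c2", "d1", "d2")
  orient <- names(which.max(table(h$orientation[h$accepted])))
  list(subfamily = best$subfamily,
       family = familyOf(library, best$subfamily),
       c1 = clusters$c1, c2 = clusters$c2,
       d1 = clusters$d1, d2 = clusters$d2,
       orientation = orient, nAligned = best$n, nTotal = length(seqs))
}

#' Single-breakpoint / insert-size consistency of a consensus profile
#'
#' Passes iff (a) every present clip cluster holds at least 80\% of its
#' category's reads and (b) the consensus distance between c1 and d2 and
#' between c2 and d1 (for whichever pairs are present) is at most
#' mu + 3*sigma of the insert size.
#'
#' @param profile From \code{\link{buildConsensusProfile}}.
#' @param stats A \code{\link{LibraryStats}}.
#' @param minClusterFraction Single-breakpoint fraction (default 0.8).
#' @return list(pass, reason).
#' @export
checkProfileConsistency <- function(profile, stats,
                                    minClusterFraction = 0.8) {
  gate <- meanInsert(stats) + 3 * sdInsert(stats)
  for (cat in c("c1", "c2")) {
    cl <- profile[[cat]]
    if (!is.null(cl) && cl$size < minClusterFraction * cl$total)
      return(list(pass = FALSE,
                  reason = sprintf("%s scattered (%d/%d in dominant cluster)",
                                   cat, cl$size, cl$total)))
  }
  pairs <- list(c("c1", "d2"), c("c2", "d1"))
  for (p in pairs) {
    a <- profile[[p[1]]]; b <- profile[[p[2]]]
    if (!is.null(a) && !is.null(b)) {
      d <- abs(a$center - b$center)
      if (d > gate)
        return(list(pass = FALSE,
                    reason = sprintf("|%s-%s| = %.0f exceeds insert gate %.0f",
                                     p[1], p[2], d, gate)))
    }
  }
  list(pass = TRUE, reason = "consistent")
}

#' Reference-repeat divergence filter
#'
#' Drops a candidate that falls inside a reference repeat of the same
#' family whose divergence from the consensus is below the threshold
#' (young same-family background copies are the dominant source of
#' alignment artifacts).
#'
#' @param chrom,pos Candidate site.
#' @param family Candidate TE family.
#' @param annotations Repeat annotations (\code{GRanges}).
#' @param maxDivPct Divergence threshold (default 5).
#' @return TRUE to keep, FALSE to drop.
#' @export
divergenceFilter <- function(chrom, pos, family, annotations, maxDivPct = 5) {
  if (is.na(family) || !length(annotations)) return(TRUE)
  site <- GRanges(chrom, IRanges(pos, pos))
  ov <- GenomicRanges::findOverlaps(site, annotations)
  hits <- S4Vectors::subjectHits(ov)
  if (!length(hits)) return(TRUE)
  mc <- mcols(annotations)[hits, , drop = FALSE]
  !any(mc$family == family & mc$divergencePct < maxDivPct)
}

#' Target-site duplication and polyA signatures of a candidate
#'
#' The TSD is the reference substring between the left-clip anchor and the
#' right-clip anchor when the right-clip anchor is larger and the gap is
#' at most \code{maxTsd} bp (both clip sides required). PolyA is called
#' from the clipped sequences: a terminal A run (T on the minus strand) of
#' at least \code{minRun} bases at purity >= \code{minPurity}.
#'
#' @param candidate A candidate site (from
#'   \code{\link{collectClipCandidates}}).
#' @param refSeq Reference sequence of the candidate's chromosome
#'   (\code{DNAString} or character).
#' @param maxTsd TSD gap cap (default 50).
#' @param minRun,minPurity PolyA acceptance (default 5, 0.8).
#' @return list(tsdSeq, tsdLen, polyALen, polyASide).
#' @export
detectTsdPolyA <- function(candidate, refSeq, maxTsd = 50L,
                           minRun = 5L, minPurity = 0.8) {
  tsdSeq <- ""; tsdLen <- 0L
  aL <- candidate$anchorL; aR <- candidate$anchorR
  if (!is.na(aL) && !is.na(aR)) {
    gap <- aR - aL
    if (gap > 0L && gap <= maxTsd) {
      tsdSeq <- as.character(Biostrings::subseq(DNAString(as.character(refSeq)),
                                                aL + 1L, aR))
      tsdLen <- gap
    }
  }
  best <- list(len = 0L, side = "none")
  for (s in c(candidate$seqsR, candidate$seqsL)) {
    sig <- polyASignal(s, minRun, minPurity)
    if (sig$len > best$len) best <- sig
  }
  list(tsdSeq = tsdSeq, tsdLen = tsdLen,
       polyALen = best$len, polyASide = best$side)
}

#' Trace the source element of a transduction (short reads)
#'
#' For a candidate with consensus support on only one side (or none at
#' all), the unexplained sequences are aligned to the indexed 3'-flank
#' windows of full-length source elements. A unique winning window yields
#' a canonical transduction when some candidate support aligned to the TE
#' consensus, an orphan transduction when none did.
#'
#' @param candidate Candidate site.
#' @param profile Consensus profile of the candidate.
#' @param unexplained Character vector of sequences not explained by the
#'   consensus (clips and discordant mates from the unexplained side).
#' @param library \code{\link{ConsensusLibrary}} with a flank index.
#' @param minIdentity,minLen Flank hit acceptance (default 90, 30).
#' @return list(kind = none/canonical/orphan, srcChrom, srcStart, srcEnd,
#'   transducedLen, ambiguous).
#' @export
detectTransduction <- function(candidate, profile, unexplained, library,
                               minIdentity = 90, minLen = 30L) {
  none <- list(kind = "none", srcChrom = NA_character_,
               srcStart = NA_integer_, srcEnd = NA_integer_,
               transducedLen = 0L, ambiguous = FALSE)
  fi <- flankIndex(library)
  fs <- flankSeqs(library)
  unexplained <- unexplained[!is.na(unexplained) & nchar(unexplained) >= minLen]
  if (!length(fi) || !length(unexplained)) return(none)
  votes <- integer(length(fi))
  extent <- integer(length(fi))
  for (w in seq_along(fi)) {
    h <- alignBatch(unexplained, fs[[w]])
    ok <- h$identity >= minIdentity & (h$tend - h$tstart + 1L) >= minLen
    votes[w] <- sum(ok)
    extent[w] <- if (any(ok)) max(h$tend[ok]) else 0L
  }
  if (max(votes) == 0L) return(none)
  winners <- which(votes == max(votes))
  if (length(winners) > 1L) { none$ambiguous <- TRUE; return(none) }
  w <- winners
  hasConsensus <- !is.null(profile$c1) || !is.null(profile$c2) ||
    !is.null(profile$d1) || !is.null(profile$d2)
  list(kind = if (hasConsensus) "canonical" else "orphan",
       srcChrom = as.character(seqnames(fi)[w]),
       srcStart = start(fi)[w], srcEnd = end(fi)[w],
       transducedLen = extent[w], ambiguous = FALSE,
       sourceFamily = mcols(fi)$sourceFamily[w])
}

#' Find the second breakpoint of a target-site deletion from read depth
#'
#' Scans the per-base depth around a one-sided candidate for a depressed
#' plateau (mean < 0.6 x flank mean over at least \code{minPlateau} bp)
#' adjacent to the site and returns the position where depth recovers.
#'
#' @param candidate Candidate site.
#' @param tbl Alignment table (depth source).
#' @param window Scan window around the site (default 5000 bp).
#' @param dropFraction Plateau threshold relative to flank depth (0.6).
#' @param minPlateau Minimum plateau length (default 50 bp).
#' @return Recovery coordinate (1-based) or NA when no plateau exists.
#' @export
resolveTargetSiteDeletion <- function(candidate, tbl, window = 5000L,
                                      dropFraction = 0.6, minPlateau = 50L) {
  site <- candidate$site
  from <- max(1L, site - window); to <- site + window
  cov <- coverageTrack(tbl, candidate$chrom, from, to)
  scanDir <- function(dir) {
    idx <- site - from + 1L
    flank <- if (dir > 0) cov[max(1L, idx - 1000L):idx]
             else cov[idx:min(length(cov), idx + 1000L)]
    fm <- mean(flank)
    if (fm <= 0) return(NA_integer_)
    i <- idx + dir
    ## allow a short ramp (reads overhang breakpoints by < read length)
    ramp <- 0L
    while (i > 1L && i < length(cov) && cov[i] >= dropFraction * fm &&
           ramp < 200L) { i <- i + dir; ramp <- ramp + 1L }
    if (cov[i] >= dropFraction * fm) return(NA_integer_)
    plateau <- 0L
    while (i > 1L && i < length(cov) && cov[i] < dropFraction * fm) {
      i <- i + dir; plateau <- plateau + 1L
    }
    if (plateau >= minPlateau) from + i - 1L else NA_integer_
  }
  down <- scanDir(1L)
  if (!is.na(down)) return(down)
  scanDir(-1L)
}

#' Call nonreference TE insertions from short-read alignments
#'
#' Full pipeline: clip-stack candidate collection, consensus profiling,
#' single-breakpoint/insert-size consistency, reference-divergence filter,
#' TSD/polyA annotation, and transduction or target-site-deletion
#' resolution for one-sided candidates. Deterministic; per-chromosome
#' sharding yields results identical to a whole-genome run.
#'
#' @param tbl Coordinate-sorted short-read alignment table.
#' @param reference Named \code{DNAStringSet} (or single sequence).
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param annotations Reference repeat annotations (\code{GRanges}), or
#'   NULL to skip the divergence filter.
#' @param thresholds From \code{\link{autoThresholds}}; computed from the
#'   data when NULL.
#' @param stats From \code{\link{estimateLibraryStats}}; computed when NULL.
#' @return An \code{\link{InsertionCallSet}}.
#' @export
callInsertionsShort <- function(tbl, reference, library, annotations = NULL,
                                thresholds = NULL, stats = NULL) {
  if (!nrow(tbl)) return(InsertionCallSet())
  if (is.null(stats)) stats <- estimateLibraryStats(tbl)
  if (is.null(thresholds)) thresholds <- autoThresholds(stats)
  cands <- collectClipCandidates(tbl, thresholds)
  if (!length(cands)) return(InsertionCallSet())
  msi <- mateSeqIndex(tbl)
  gate <- meanInsert(stats) + 3 * sdInsert(stats)
  calls <- list()
  for (cand in cands) {
    refSeq <- if (is(reference, "DNAStringSet")) reference[[cand$chrom]]
              else reference
    dm <- discordantMates(tbl, cand$chrom, cand$site, gate, msi)
    prof <- buildConsensusProfile(cand, dm$left, dm$right, library)
    twoSided <- !is.null(prof$c1) && !is.null(prof$c2)
    family <- prof$family; subfamily <- prof$subfamily
    td <- list(kind = "none", srcChrom = NA_character_,
               srcStart = NA_integer_, srcEnd = NA_integer_)
    tsdel <- c(NA_integer_, NA_integer_)
    if (twoSided) {
      cons <- checkProfileConsistency(prof, stats)
      if (!cons$pass) next
    } else {
      ## one-sided (or consensus-free) path: transduction, then
      ## target-site deletion
      explainedR <- !is.null(prof$c1)
      unexpl <- c(if (explainedR) cand$seqsL else cand$seqsR,
                  if (explainedR) dm$right else dm$left)
      td <- detectTransduction(cand, prof, unexpl, library)
      if (td$kind != "none") {
        if (is.na(family)) family <- td$sourceFamily
      } else {
        second <- resolveTargetSiteDeletion(cand, tbl)
        if (is.na(second)) next
        tsdel <- sort(c(cand$site, second))
      }
      if ((cand$countR + cand$countL) < thresholds$minClipReads) next
    }
    if (!is.null(annotations) &&
        !divergenceFilter(cand$chrom, cand$site, family, annotations,
                          thresholds$maxRefDivergencePct)) next
    sig <- detectTsdPolyA(cand, refSeq)
    anchors <- c(cand$anchorL, cand$anchorR)
    anchors <- anchors[!is.na(anchors)]
    gr <- GRanges(cand$chrom, IRanges(cand$site, width = 1L))
    mcols(gr) <- DataFrame(
      family = family, subfamily = subfamily,
      leftBp = min(anchors), rightBp = max(anchors),
      orientation = if (is.na(prof$orientation)) "+" else prof$orientation,
      tsdSeq = sig$tsdSeq, tsdLen = sig$tsdLen,
      polyALen = sig$polyALen, polyASide = sig$polyASide,
      tdKind = td$kind, tdChrom = td$srcChrom,
      tdStart = td$srcStart, tdEnd = td$srcEnd,
      clipLeft = cand$countR, clipRight = cand$countL,
      disc = dm$n, spanning = 0L,
      tsdelStart = tsdel[1], tsdelEnd = tsdel[2],
      genotype = NA_character_, gq = NA_real_,
      provenance = "short", insSeq = NA_character_)
    calls[[length(calls) + 1L]] <- gr
  }
  if (!length(calls)) return(InsertionCallSet())
  out <- InsertionCallSet(suppressWarnings(do.call(c, calls)))
  ## a target-site deletion produces clip stacks at both junctions; keep
  ## the call anchored at the insertion junction and drop the echo call
  ## at the distal (depth-recovery) junction
  gr <- insertionCalls(out)
  if (length(gr) > 1L) {
    drop <- logical(length(gr))
    mc <- mcols(gr)
    for (i in which(!is.na(mc$tsdelStart))) {
      inside <- as.character(seqnames(gr)) == as.character(seqnames(gr)[i]) &
        start(gr) > mc$tsdelStart[i] - 10L &
        start(gr) <= mc$tsdelEnd[i] + 10L &
        start(gr) > start(gr)[i]    # keep the leftmost (insertion) junction
      drop <- drop | inside
    }
    out <- InsertionCallSet(gr[!drop])
  }
  out
}
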