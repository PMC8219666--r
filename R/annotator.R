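## Post-assembly structural annotation: L1 internal structure, processed
## pseudogenes, centromeric ghost L1s, TE-insertion-mediated SVs, and
## dimorphic HERVs.

#' Annotate the internal structure of an L1 insertion
#'
#' The insertion is split-aligned onto the L1 consensus (best local part,
#' then the remaining terminal segment). A contiguous full-coverage
#' alignment is a full-length copy and a contiguous suffix a 5'-truncated
#' copy; two same-orientation parts separated by a consensus gap strictly
#' greater than \code{minDeletionGap} indicate an internal deletion;
#' opposite orientations indicate an internal inversion (twin priming);
#' both signals together are deletion_and_inversion.
#'
#' @param insertionSeq Insertion sequence (polyA tail tolerated).
#' @param l1Consensus L1 consensus sequence.
#' @param minDeletionGap Strict gap threshold (default 20 bp).
#' @param minPart Minimum split-part length (default 30 bp).
#' @param fullLengthFraction Consensus coverage for full length (0.95).
#' @return list(category, segments (data.frame qstart, qend, tstart,
#'   tend, orientation), deletionGap).
#' @export
annotateL1Structure <- function(insertionSeq, l1Consensus,
                                minDeletionGap = 20L, minPart = 30L,
                                fullLengthFraction = 0.95) {
  insertionSeq <- as.character(insertionSeq)
  l1Consensus <- as.character(l1Consensus)
  consLen <- nchar(l1Consensus)
  a1 <- alignPair(insertionSeq, l1Consensus, mode = "local")
  if (a1$identity < 80 || a1$alnLen < minPart)
    stop("sequence does not align to the L1 consensus")
  ## primary alignment, oriented; split it at internal query-gap runs
  ## longer than the deletion threshold (an affine aligner bridges an
  ## internal deletion as one alignment with a long consensus gap)
  q1 <- if (a1$orientation == "-") revComp(insertionSeq) else insertionSeq
  pa <- Biostrings::pairwiseAlignment(DNAString(q1), DNAString(l1Consensus),
                                      type = "local",
                                      substitutionMatrix = .alnMat(),
                                      gapOpening = 4, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  tstart <- Biostrings::start(Biostrings::subject(pa))
  tpos <- tstart - 1L
  segStartT <- tstart
  parts <- data.frame()
  gapRun <- 0L
  isGap <- p == "-"
  subjCols <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                       "")[[1L]] != "-"
  lastT <- tstart - 1L
  for (k in seq_along(p)) {
    if (subjCols[k]) tpos <- tpos + 1L
    if (isGap[k] && subjCols[k]) {
      gapRun <- gapRun + 1L
    } else if (!isGap[k]) {
      if (gapRun > minDeletionGap) {
        parts <- rbind(parts, data.frame(tstart = segStartT,
                                         tend = tpos - gapRun - 1L,
                                         orientation = a1$orientation))
        segStartT <- tpos
      }
      gapRun <- 0L
      lastT <- tpos
    }
  }
  parts <- rbind(parts, data.frame(tstart = segStartT, tend = lastT,
                                   orientation = a1$orientation))
  parts$qstart <- NA_integer_; parts$qend <- NA_integer_
  parts$qstart[1] <- a1$qstart; parts$qend[nrow(parts)] <- a1$qend
  ## realign the larger unaligned terminal segment (opposite-orientation
  ## part of a twin-priming product)
  segs <- list(c(1L, a1$qstart - 1L),
               c(a1$qend + 1L, nchar(insertionSeq)))
  for (s in segs) {
    if (s[2] - s[1] + 1L < minPart) next
    sub <- substr(insertionSeq, s[1], s[2])
    if (polyASignal(sub)$len >= 0.8 * nchar(sub)) next  # polyA tail
    a2 <- alignPair(sub, l1Consensus, mode = "local")
    if (a2$identity >= 80 && a2$alnLen >= minPart) {
      parts <- rbind(parts, data.frame(
        tstart = a2$tstart, tend = a2$tend, orientation = a2$orientation,
        qstart = s[1] + a2$qstart - 1L, qend = s[1] + a2$qend - 1L))
    }
  }
  parts <- parts[order(parts$tstart), , drop = FALSE]
  rownames(parts) <- NULL
  gaps <- if (nrow(parts) > 1L)
    parts$tstart[-1L] - parts$tend[-nrow(parts)] - 1L else integer(0)
  maxGap <- if (length(gaps)) max(gaps) else NA_integer_
  sameOrient <- length(unique(parts$orientation)) == 1L
  if (!sameOrient) {
    hasDel <- !is.na(maxGap) && maxGap > minDeletionGap
    return(list(category = if (hasDel) "deletion_and_inversion"
                           else "internal_inversion",
                segments = parts,
                deletionGap = if (hasDel) maxGap else NA_integer_))
  }
  if (!is.na(maxGap) && maxGap > minDeletionGap)
    return(list(category = "internal_deletion", segments = parts,
                deletionGap = maxGap))
  ## contiguous (all gaps <= threshold): full or truncated by coverage
  covered <- parts$tend[nrow(parts)] - parts$tstart[1L] + 1L
  cat1 <- if (covered >= fullLengthFraction * consLen) "full_length"
          else "truncated_5p"
  list(category = cat1, segments = parts, deletionGap = NA_integer_)
}

## Mapping-quality equivalent of an exon hit: scaled score margin over the
## best competing exon hit on the same region of the insertion.
.mapqEquiv <- function(score, secondScore) {
  if (is.na(secondScore)) return(60L)
  as.integer(min(60, max(0, (score - secondScore) / 2)))
}

#' Detect a processed-pseudogene insertion
#'
#' Calls a pseudogene when at least \code{minExons} exons of a single gene
#' tile >= \code{minCoverage} of the insertion (after removing the
#' terminal polyA/T tail) in transcript order with no intervening
#' sequence, each exon hit is unique (mapping-quality equivalent >=
#' \code{minMapqEquiv}), and a terminal polyA/T run of >= \code{minPolyA}
#' bases exists.
#'
#' @param insertionSeq Assembled insertion sequence.
#' @param exonIndex data.frame from \code{\link{readExonsBed}} (columns
#'   \code{gene}, \code{exon}, \code{seq}, coordinates).
#' @param minMapqEquiv Exon-hit uniqueness threshold (default 30).
#' @param minExons,minCoverage Tiling requirements (default 2, 0.8).
#' @param minPolyA Minimum polyA/T run (default 5).
#' @param site,transcripts Optional insertion site (list(chrom, pos)) and
#'   transcript table for region classification.
#' @return list(gene, exons, polyALen, regionClass) or NULL.
#' @export
detectPseudogene <- function(insertionSeq, exonIndex, minMapqEquiv = 30L,
                             minExons = 2L, minCoverage = 0.8,
                             minPolyA = 5L, site = NULL,
                             transcripts = NULL) {
  pa <- polyASignal(insertionSeq, minRun = minPolyA)
  if (pa$len < minPolyA) return(NULL)
  ## strip the tail (plus any short overhang such as a TSD copy beyond
  ## it): cut at the run of the detected tail base nearest the terminus
  n <- nchar(insertionSeq)
  core <- NULL
  if (pa$side == "right") {
    wfrom <- max(1L, n - 60L)
    w <- substr(insertionSeq, wfrom, n)
    base <- if (windowPolyRun(insertionSeq, "A", "right") >=
                  windowPolyRun(insertionSeq, "T", "right")) "A" else "T"
    m <- gregexpr(sprintf("%s{%d,}", base, minPolyA), w)[[1L]]
    core <- if (m[1] > 0)
      substr(insertionSeq, 1L, wfrom + m[length(m)] - 2L)
    else substr(insertionSeq, 1L, n - pa$len)
  } else {
    wto <- min(n, 60L)
    w <- substr(insertionSeq, 1L, wto)
    base <- if (windowPolyRun(insertionSeq, "T", "left") >=
                  windowPolyRun(insertionSeq, "A", "left")) "T" else "A"
    m <- gregexpr(sprintf("%s{%d,}", base, minPolyA), w)[[1L]]
    cut <- if (m[1] > 0) m[1] + attr(m, "match.length")[1] else pa$len + 1L
    core <- substr(insertionSeq, cut, n)
  }
  if (nchar(core) < 50L) return(NULL)
  hits <- list()
  for (i in seq_len(nrow(exonIndex))) {
    ex <- exonIndex[i, ]
    a <- alignPair(ex$seq, core, mode = "local")
    if (a$identity >= 90 && a$alnLen >= 0.9 * nchar(ex$seq)) {
      hits[[length(hits) + 1L]] <- data.frame(
        gene = ex$gene, exon = ex$exon, score = a$score,
        qstart = a$tstart, qend = a$tend, orientation = a$orientation)
    }
  }
  if (!length(hits)) return(NULL)
  hits <- do.call(rbind, hits)
  ## uniqueness: best competing hit overlapping the same core interval
  hits$mapq <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    comp <- hits[-i, , drop = FALSE]
    ovl <- pmin(comp$qend, h$qend) - pmax(comp$qstart, h$qstart) + 1L
    comp <- comp[ovl >= 0.5 * (h$qend - h$qstart + 1L), , drop = FALSE]
    .mapqEquiv(h$score, if (nrow(comp)) max(comp$score) else NA)
  }, 0L)
  ok <- hits[hits$mapq >= minMapqEquiv, , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  byGene <- split(ok, ok$gene)
  counts <- vapply(byGene, nrow, 0L)
  gene <- names(counts)[which.max(counts)]
  gh <- byGene[[gene]][order(byGene[[gene]]$qstart), , drop = FALSE]
  if (nrow(gh) < minExons) return(NULL)
  ## transcript order and contiguity on the insertion
  orderedFwd <- !is.unsorted(gh$exon)
  orderedRev <- !is.unsorted(rev(gh$exon))
  if (!orderedFwd && !orderedRev) return(NULL)
  gaps <- gh$qstart[-1L] - gh$qend[-nrow(gh)] - 1L
  if (any(gaps > 20L)) return(NULL)
  coverage <- sum(gh$qend - gh$qstart + 1L) / nchar(core)
  if (coverage < minCoverage) return(NULL)
  regionClass <- "intergenic"
  if (!is.null(site) && !is.null(transcripts)) {
    inTx <- transcripts$chrom == site$chrom &
      site$pos >= transcripts$txStart & site$pos <= transcripts$txEnd
    if (any(inTx)) {
      regionClass <- "intronic"
      for (i in which(inTx)) {
        es <- transcripts$exonStarts[[i]]; ee <- transcripts$exonEnds[[i]]
        if (any(site$pos >= es & site$pos <= ee)) regionClass <- "exonic"
      }
    }
  }
  list(gene = gene, exons = gh[, c("exon", "qstart", "qend", "mapq")],
       polyALen = pa$len, regionClass = regionClass)
}

#' Find centromeric "ghost" full-length L1 copies
#'
#' Reads aligning to a reference full-length L1 donor with clips on both
#' flanks carry the true (satellite) flanking sequence of a nonreference
#' copy in their clipped parts. Clipped sequences are all-vs-all aligned
#' and single-linkage clustered (>= \code{clusterIdentity}\% identity over
#' >= \code{clusterMinLen} bp); each cluster's flanks are assembled and
#' classified, and a cluster is reported as a ghost L1 iff any flank is
#' labeled Alpha, Beta or HSATII satellite.
#'
#' @param tbl Long-read alignment table.
#' @param fullLengthL1s \code{GRanges} of reference full-length L1 donors.
#' @param satelliteLibrary \code{\link{ConsensusLibrary}} containing the
#'   satellite classes (families Alpha/Beta/HSATII).
#' @param minClip Minimum flank clip length (default 100 bp).
#' @param clusterIdentity,clusterMinLen Similarity clustering (85, 200).
#' @param minClusterSize Minimum reads per cluster (default 2).
#' @return List of ghost clusters (donor index, read rows, flank labels,
#'   assembled flank contigs). Total cluster count (before the satellite
#'   gate) in \code{attr(, "nClusters")}.
#' @export
findGhostL1 <- function(tbl, fullLengthL1s, satelliteLibrary,
                        minClip = 100L, clusterIdentity = 85,
                        clusterMinLen = 200L, minClusterSize = 2L) {
  stopifnot(length(fullLengthL1s) > 0)
  satFams <- c("Alpha", "Beta", "HSATII")
  out <- list(); nClusters <- 0L
  for (d in seq_along(fullLengthL1s)) {
    don <- fullLengthL1s[d]
    sel <- which(tbl$isMapped & !tbl$isSupp &
                   tbl$chrom == as.character(seqnames(don)) &
                   tbl$pos <= end(don) & tbl$endpos >= start(don) &
                   tbl$clipL >= minClip & tbl$clipR >= minClip)
    if (length(sel) < minClusterSize) next
    leftSegs <- vapply(sel, function(i)
      clipSeq(tbl$seq[i], tbl$clipL[i], tbl$clipR[i], "left"), "")
    rightSegs <- vapply(sel, function(i)
      clipSeq(tbl$seq[i], tbl$clipL[i], tbl$clipR[i], "right"), "")
    n <- length(sel)
    ## union-find single linkage on flank similarity
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    similar <- function(a, b) {
      h <- alignPair(a, b, mode = "local")
      h$identity >= clusterIdentity && h$alnLen >= clusterMinLen
    }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      if (similar(leftSegs[i], leftSegs[j]) ||
          similar(rightSegs[i], rightSegs[j]))
        parent[find(j)] <- find(i)
    }
    comp <- vapply(seq_len(n), find, 0L)
    for (k in unique(comp)) {
      members <- which(comp == k)
      if (length(members) < minClusterSize) next
      nClusters <- nClusters + 1L
      leftContig <- assembleLocal(leftSegs[members])$contig
      rightContig <- assembleLocal(rightSegs[members])$contig
      lab <- function(ctg) {
        if (nchar(ctg) < 30L) return(NA_character_)
        h <- classifySequence(ctg, satelliteLibrary, minCoveragePct = 30)
        if (is.null(h)) NA_character_ else h$family
      }
      labs <- c(left = lab(leftContig), right = lab(rightContig))
      if (any(labs %in% satFams)) {
        out[[length(out) + 1L]] <- list(
          donor = d, rows = sel[members], flankLabels = labs,
          leftContig = leftContig, rightContig = rightContig)
      }
    }
  }
  attr(out, "nClusters") <- nClusters
  out
}

#' Pair SV breakpoints by reciprocal flank-contig alignment
#'
#' A left breakpoint (reads left-clipped there) pairs with a right
#' breakpoint (reads right-clipped) when the reference flank of each
#' aligns to the assembled clipped-side contig of the other; each
#' breakpoint takes at most one partner (best reciprocal score).
#'
#' @param leftBps,rightBps Integer positions of left-/right-clip
#'   breakpoints.
#' @param refSeq Reference chromosome sequence.
#' @param leftContigs,rightContigs Assembled contigs of the clipped parts
#'   at each breakpoint (parallel to the position vectors).
#' @param flankLen Flank length (default 500).
#' @param minIdentity,minLen Acceptance (80, 200).
#' @return data.frame(leftBp, rightBp, score) of paired breakpoints.
#' @export
pairSvBreakpoints <- function(leftBps, rightBps, refSeq,
                              leftContigs, rightContigs, flankLen = 500L,
                              minIdentity = 80, minLen = 200L) {
  refSeq <- DNAString(as.character(refSeq))
  hit <- function(flank, contig) {
    a <- alignPair(flank, contig, mode = "local")
    if (a$identity >= minIdentity && a$alnLen >= minLen) a$score else NA_real_
  }
  pairs <- list()
  for (i in seq_along(leftBps)) {
    fA <- as.character(Biostrings::subseq(refSeq, leftBps[i] + 1L,
                                          min(length(refSeq),
                                              leftBps[i] + flankLen)))
    for (j in seq_along(rightBps)) {
      fB <- as.character(Biostrings::subseq(refSeq,
                                            max(1L, rightBps[j] - flankLen + 1L),
                                            rightBps[j]))
      s1 <- hit(fA, rightContigs[[j]])
      s2 <- hit(fB, leftContigs[[i]])
      if (!is.na(s1) && !is.na(s2))
        pairs[[length(pairs) + 1L]] <- data.frame(
          leftBp = leftBps[i], rightBp = rightBps[j], score = s1 + s2)
    }
  }
  if (!length(pairs))
    return(data.frame(leftBp = integer(0), rightBp = integer(0),
                      score = numeric(0)))
  p <- do.call(rbind, pairs)
  p <- p[order(-p$score), , drop = FALSE]
  keep <- !duplicated(p$leftBp) & !duplicated(p$rightBp)
  p <- p[keep & !duplicated(paste(p$leftBp, p$rightBp)), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Classify a TE-insertion-mediated structural variant
#'
#' Given paired breakpoints and a spanning contig: a deletion when the
#' internal sequence is fully TE and the flank reference gap is at least
#' \code{minDeletionSpan} bp (beyond target-site-duplication scale); an
#' inversion when the non-TE remainder aligns to the reference between
#' the flanks in the opposite orientation; a duplication when the clipped
#' sides align to the same reference interval.
#'
#' @param rightClipBp,leftClipBp The paired breakpoints: position where
#'   reads stop aligning (right clips) and where they resume (left clips).
#' @param contig Spanning contig across the rearranged junction.
#' @param refSeq Reference chromosome sequence.
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param flankLen Flank length (default 500).
#' @param minDeletionSpan TSD disambiguation (default 100 bp).
#' @return list(svType in \{deletion, duplication, inversion,
#'   unclassified\}, teFamily, spanStart, spanEnd, evidence).
#' @export
classifyTeMediatedSv <- function(rightClipBp, leftClipBp, contig, refSeq,
                                 library, flankLen = 500L,
                                 minDeletionSpan = 100L) {
  refSeq <- DNAString(as.character(refSeq))
  L0 <- min(rightClipBp, leftClipBp)
  R0 <- max(rightClipBp, leftClipBp)
  fL <- as.character(Biostrings::subseq(refSeq, max(1L, L0 - flankLen + 1L), L0))
  fR <- as.character(Biostrings::subseq(refSeq, R0 + 1L,
                                        min(length(refSeq), R0 + flankLen)))
  unclassified <- list(svType = "unclassified", teFamily = NA_character_,
                       spanStart = NA_integer_, spanEnd = NA_integer_,
                       evidence = "flank alignment failed")
  tryCtg <- function(ctg) {
    aL <- alignPair(fL, ctg, mode = "local")
    aR <- alignPair(fR, ctg, mode = "local")
    if (aL$identity < 80 || aR$identity < 80 ||
        aL$orientation != "+" || aR$orientation != "+" ||
        aR$tstart <= aL$tend) return(NULL)
    list(ctg = ctg, aL = aL, aR = aR)
  }
  got <- tryCtg(contig)
  if (is.null(got)) got <- tryCtg(revComp(contig))
  if (is.null(got)) return(unclassified)
  internal <- substr(got$ctg, got$aL$tend + 1L, got$aR$tstart - 1L)
  if (nchar(internal) < 50L) return(unclassified)
  ## the TE may be a minor part of the internal sequence (the rest being
  ## rearranged reference), so the coverage gate is relaxed here
  te <- classifySequence(internal, library, minCoveragePct = 5)
  teFamily <- if (is.null(te)) NA_character_ else te$family
  residuals <- character(0)
  if (!is.null(te)) {
    if (te$qstart - 1L >= 50L)
      residuals <- c(residuals, substr(internal, 1L, te$qstart - 1L))
    if (nchar(internal) - te$qend >= 50L)
      residuals <- c(residuals, substr(internal, te$qend + 1L,
                                       nchar(internal)))
  } else residuals <- internal
  if (!length(residuals)) {
    if (R0 - L0 >= minDeletionSpan)
      return(list(svType = "deletion", teFamily = teFamily,
                  spanStart = L0 + 1L, spanEnd = R0,
                  evidence = "internal fully TE, flanks apart"))
    return(list(svType = "unclassified", teFamily = teFamily,
                spanStart = NA_integer_, spanEnd = NA_integer_,
                evidence = "flank gap below TSD scale"))
  }
  ## align residuals to the reference between (around) the flanks
  winS <- max(1L, L0 - 100L); winE <- min(length(refSeq), R0 + 100L)
  win <- as.character(Biostrings::subseq(refSeq, winS, winE))
  hits <- lapply(residuals, function(r) alignPair(r, win, mode = "local"))
  ok <- vapply(hits, function(h) h$identity >= 80 && h$alnLen >= 50L, TRUE)
  hits <- hits[ok]
  if (!length(hits))
    return(list(svType = "unclassified", teFamily = teFamily,
                spanStart = NA_integer_, spanEnd = NA_integer_,
                evidence = "residual unaligned to reference"))
  orient <- vapply(hits, `[[`, "", "orientation")
  if (any(orient == "-")) {
    h <- hits[[which(orient == "-")[1]]]
    return(list(svType = "inversion", teFamily = teFamily,
                spanStart = winS + h$tstart - 1L,
                spanEnd = winS + h$tend - 1L,
                evidence = "residual aligns reference in - orientation"))
  }
  if (length(hits) >= 2L) {
    iv <- vapply(hits, function(h) c(h$tstart, h$tend), c(0, 0))
    ovl <- min(iv[2, ]) - max(iv[1, ]) + 1
    minw <- min(iv[2, ] - iv[1, ] + 1)
    if (ovl >= 0.5 * minw)
      return(list(svType = "duplication", teFamily = teFamily,
                  spanStart = winS + min(iv[1, ]) - 1L,
                  spanEnd = winS + max(iv[2, ]) - 1L,
                  evidence = "clipped sides align the same reference interval"))
  }
  list(svType = "unclassified", teFamily = teFamily,
       spanStart = NA_integer_, spanEnd = NA_integer_,
       evidence = "residual pattern unrecognized")
}

#' Detect TE-insertion-mediated SVs from long-read alignments
#'
#' Orchestrates the SV path: clip evidence is harvested and grouped; each
#' breakpoint's clipped side is assembled into a contig; breakpoints are
#' paired by the reciprocal flank-contig condition
#' (\code{\link{pairSvBreakpoints}}); and each pair is classified
#' (\code{\link{classifyTeMediatedSv}}) from a contig spanning the
#' rearranged junction.
#'
#' @param tbl Long-read alignment table.
#' @param reference Named \code{DNAStringSet} or single sequence.
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param minSupport Minimum reads per breakpoint (default 2).
#' @return List of classified SVs (svType, teFamily, spanStart, spanEnd,
#'   leftBp = left-clip breakpoint, rightBp = right-clip breakpoint).
#' @export
detectTeMediatedSv <- function(tbl, reference, library, minSupport = 2L) {
  ev <- harvestBreakpointEvidence(tbl)
  groups <- groupClipEvents(ev)
  out <- list(); bps <- list(); directBps <- integer(0)
  ## a deletion D operation >= this length adjacent to an insertion
  ## operation marks a junction observed in a single spanning alignment
  bigDeletionOf <- function(rows) {
    ds <- unlist(lapply(unique(rows), function(i) {
      ops <- explodeCigarOps(tbl$cigar[i])[[1L]]
      lens <- explodeCigarOpLengths(tbl$cigar[i])[[1L]]
      lens[ops == "D" & lens >= 100L]
    }))
    if (length(ds) >= minSupport) as.integer(stats::median(ds)) else NA_integer_
  }
  for (g in groups) {
    ge <- ev[g$eventIdx, , drop = FALSE]
    chrom <- g$chrom
    refSeq <- if (is(reference, "DNAStringSet")) reference[[chrom]]
              else reference
    insEv <- ge[ge$kind == "internal-insertion", , drop = FALSE]
    if (nrow(insEv) >= minSupport) {
      ## spanning-alignment representation: I op next to a large D op
      d <- bigDeletionOf(insEv$row)
      if (!is.na(d)) {
        A <- g$medianSite; B <- A + d
        spanEv <- ge[!duplicated(ge$qname), , drop = FALSE]
        asm <- assembleLocal(localAssemblyReads(tbl, spanEv))
        if (!asm$failed) {
          cls <- classifyTeMediatedSv(rightClipBp = A, leftClipBp = B,
                                      contig = asm$contig,
                                      refSeq = refSeq, library = library)
          if (cls$svType != "unclassified") {
            cls$leftBp <- B; cls$rightBp <- A; cls$chrom <- chrom
            out[[length(out) + 1L]] <- cls
            directBps <- c(directBps, A, B)
            next
          }
        }
      }
    }
    for (kd in c("left-clip", "right-clip")) {
      ke <- ge[ge$kind == kd, , drop = FALSE]
      ke <- ke[!duplicated(ke$qname), , drop = FALSE]
      if (nrow(ke) < minSupport) next
      asm <- assembleLocal(ke$segment)   # the clipped parts themselves
      if (asm$failed) next
      bps[[length(bps) + 1L]] <- list(
        kind = kd, pos = g$medianSite, chrom = chrom,
        contig = asm$contig, events = ke)
    }
  }
  if (!length(bps)) return(out)
  for (chrom in unique(vapply(bps, `[[`, "", "chrom"))) {
    refSeq <- if (is(reference, "DNAStringSet")) reference[[chrom]]
              else reference
    sub <- bps[vapply(bps, `[[`, "", "chrom") == chrom]
    keep <- vapply(sub, function(x)
      !length(directBps) || min(abs(directBps - x$pos)) > 50L, TRUE)
    sub <- sub[keep]
    kinds <- vapply(sub, `[[`, "", "kind")
    lefts <- sub[kinds == "left-clip"]
    rights <- sub[kinds == "right-clip"]
    if (!length(lefts) || !length(rights)) next
    pairs <- pairSvBreakpoints(
      leftBps = vapply(lefts, function(x) x$pos, 0L),
      rightBps = vapply(rights, function(x) x$pos, 0L),
      refSeq = refSeq,
      leftContigs = lapply(lefts, `[[`, "contig"),
      rightContigs = lapply(rights, `[[`, "contig"))
    for (i in seq_len(nrow(pairs))) {
      li <- which(vapply(lefts, function(x) x$pos, 0L) == pairs$leftBp[i])[1]
      ri <- which(vapply(rights, function(x) x$pos, 0L) == pairs$rightBp[i])[1]
      spanEv <- rbind(lefts[[li]]$events, rights[[ri]]$events)
      spanEv <- spanEv[!duplicated(spanEv$qname), , drop = FALSE]
      ## a duplication junction (right-clip bp beyond left-clip bp) needs
      ## contig context reaching upstream of the left breakpoint
      ctx <- min(8000L, max(0L, pairs$rightBp[i] - pairs$leftBp[i]) + 2000L)
      asm <- assembleLocal(localAssemblyReads(tbl, spanEv, context = ctx))
      if (asm$failed) next
      cls <- classifyTeMediatedSv(rightClipBp = pairs$rightBp[i],
                                  leftClipBp = pairs$leftBp[i],
                                  contig = asm$contig, refSeq = refSeq,
                                  library = library)
      cls$leftBp <- pairs$leftBp[i]; cls$rightBp <- pairs$rightBp[i]
      cls$chrom <- chrom
      out[[length(out) + 1L]] <- cls
    }
  }
  out
}

#' Detect dimorphic HERV copies at solo-LTR loci
#'
#' For each reference solo LTR: boundary-clipped (or spanning) reads are
#' assembled; the reference flanks outside the LTR are aligned to the
#' contig and the sequence between them is the candidate copy; the LTR
#' consensus must align to both ends of the candidate and the middle must
#' classify as HERV. The internal deletion length is the HERV-internal
#' consensus length minus the observed middle length when that difference
#' exceeds 100 bp.
#'
#' @param tbl Long-read alignment table.
#' @param soloLtrs \code{GRanges} of reference solo-LTR loci (mcols
#'   \code{subfamily} naming the LTR consensus record).
#' @param library \code{\link{ConsensusLibrary}} containing the LTR and
#'   HERV-internal records.
#' @param reference Named \code{DNAStringSet} or single sequence.
#' @param minClip Minimum boundary clip (default 30).
#' @param flankLen Flank length outside the locus (default 500).
#' @return List of HERV calls: locus index, \code{family},
#'   \code{internalLen}, \code{internalDeletionLen} (NA when < 100),
#'   \code{candidateLen}, \code{contig}. Skipped-locus count in
#'   \code{attr(, "skipped")}.
#' @export
detectDimorphicHerv <- function(tbl, soloLtrs, library, reference,
                                minClip = 30L, flankLen = 500L) {
  out <- list(); skipped <- 0L
  internalRec <- which(familyOf(library, names(consensusSeqs(library))) == "HERV")
  expectedInternal <- if (length(internalRec))
    max(Biostrings::width(consensusSeqs(library))[internalRec]) else NA_integer_
  allEv <- harvestBreakpointEvidence(tbl, minClip = minClip)
  for (li in seq_along(soloLtrs)) {
    locus <- soloLtrs[li]
    chrom <- as.character(seqnames(locus))
    refSeq <- if (is(reference, "DNAStringSet")) reference[[chrom]]
              else reference
    s <- start(locus); e <- end(locus)
    ev <- allEv
    ev <- ev[ev$chrom == chrom & ev$anchor >= s - 150L &
               ev$anchor <= e + 150L, , drop = FALSE]
    ev <- ev[!duplicated(ev$row), , drop = FALSE]
    if (nrow(ev) < 2L) { skipped <- skipped + 1L; next }
    asm <- assembleLocal(localAssemblyReads(tbl, ev))
    if (asm$failed) { skipped <- skipped + 1L; next }
    ctg <- asm$contig
    fL <- as.character(Biostrings::subseq(DNAString(as.character(refSeq)),
                                          max(1L, s - flankLen), s - 1L))
    fR <- as.character(Biostrings::subseq(DNAString(as.character(refSeq)),
                                          e + 1L,
                                          min(nchar(as.character(refSeq)),
                                              e + flankLen)))
    tryCtg <- function(ct) {
      aL <- alignPair(fL, ct, mode = "local")
      aR <- alignPair(fR, ct, mode = "local")
      if (aL$identity < 80 || aR$identity < 80 ||
          aL$orientation != "+" || aR$orientation != "+" ||
          aR$tstart <= aL$tend) return(NULL)
      substr(ct, aL$tend + 1L, aR$tstart - 1L)
    }
    cand <- tryCtg(ctg)
    if (is.null(cand)) cand <- tryCtg(revComp(ctg))
    if (is.null(cand) || nchar(cand) < 100L) next
    ltrName <- mcols(locus)$subfamily
    if (!ltrName %in% names(consensusSeqs(library))) next
    ltr <- consensusSeqs(library)[[ltrName]]
    aHead <- alignPair(ltr, substr(cand, 1L, min(nchar(cand),
                                                 length(ltr) + 200L)))
    tailFrom <- max(1L, nchar(cand) - length(ltr) - 200L)
    aTail <- alignPair(ltr, substr(cand, tailFrom, nchar(cand)))
    okHead <- aHead$identity >= 80 && aHead$alnLen >= 0.6 * length(ltr) &&
      aHead$tstart <= 100L
    okTail <- aTail$identity >= 80 && aTail$alnLen >= 0.6 * length(ltr) &&
      (tailFrom + aTail$tend - 1L) >= nchar(cand) - 100L
    if (!okHead || !okTail) next
    midFrom <- aHead$tend + 1L
    midTo <- tailFrom + aTail$tstart - 2L
    if (midTo - midFrom + 1L < 100L) next
    middle <- substr(cand, midFrom, midTo)
    hit <- classifySequence(middle, library, minCoveragePct = 25)
    if (is.null(hit) || hit$family != "HERV") next
    obs <- nchar(middle)
    del <- if (!is.na(expectedInternal) && expectedInternal - obs > 100L)
      expectedInternal - obs else NA_integer_
    out[[length(out) + 1L]] <- list(
      locus = li, family = hit$family, subfamily = hit$subfamily,
      internalLen = obs, internalDeletionLen = del,
      candidateLen = nchar(cand), contig = ctg)
  }
  attr(out, "skipped") <- skipped
  out
}
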