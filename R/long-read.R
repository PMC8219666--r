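## Insertion discovery from long-read alignments.
##
## Long reads clip at variable positions around a breakpoint, so clip
## events are grouped within 75 bp and a group is rejected when the RMS
## distance of clip anchors from the median anchor exceeds 45 bp. Reads
## fully spanning an insertion contribute CIGAR insertion operations
## instead of clips. Supporting reads are locally assembled (built-in
## backbone-and-polish assembler; the contract is pluggable), the
## reference flanks of the site are aligned to the contig, and the contig
## sequence strictly between the flank hits is the insertion sequence.

#' Harvest clip and CIGAR-insertion evidence from long reads
#'
#' One event per qualifying soft-clip terminus (>= \code{minClip} bp) or
#' CIGAR \code{I} operation (>= \code{minInsertion} bp); segments are the
#' clipped / inserted bases taken verbatim from the read sequence.
#'
#' @param tbl Coordinate-sorted long-read alignment table.
#' @param minClip Minimum terminal clip length (default 30).
#' @param minInsertion Minimum internal insertion length (default 100).
#' @return data.frame with \code{qname}, \code{chrom}, \code{anchor}
#'   (1-based reference position of the junction), \code{kind}
#'   (left-clip / right-clip / internal-insertion), \code{segment},
#'   \code{segmentLen}, \code{row} (source row in \code{tbl}). Records
#'   without a stored sequence are skipped; their count is in
#'   \code{attr(, "skippedNoSeq")}.
#' @export
harvestBreakpointEvidence <- function(tbl, minClip = 30L,
                                      minInsertion = 100L) {
  checkSorted(tbl)
  ## supplementary records carry the partner-side clips of split
  ## alignments (SV junctions), so they are kept
  use <- which(tbl$isMapped & !tbl$isDup)
  noSeq <- is.na(tbl$seq[use]) | tbl$seq[use] %in% c("", "*")
  skipped <- sum(noSeq & (tbl$clipL[use] >= minClip |
                            tbl$clipR[use] >= minClip |
                            grepl("I", tbl$cigar[use])))
  if (skipped > 0)
    warning(skipped, " records without stored sequence skipped")
  use <- use[!noSeq]
  out <- list()
  for (i in use) {
    cigar <- tbl$cigar[i]
    ops <- explodeCigarOps(cigar)[[1L]]
    lens <- explodeCigarOpLengths(cigar)[[1L]]
    seq <- tbl$seq[i]
    qpos <- 1L                       # next query base
    rpos <- tbl$pos[i]               # next reference base
    for (k in seq_along(ops)) {
      op <- ops[k]; L <- lens[k]
      if (op %in% c("S", "H")) {
        if (op == "S" && L >= minClip) {
          if (k == 1L) {
            out[[length(out) + 1L]] <- data.frame(
              qname = tbl$qname[i], chrom = tbl$chrom[i],
              anchor = tbl$pos[i] - 1L, kind = "left-clip",
              segment = substr(seq, 1L, L), segmentLen = L, row = i,
              qstart = 1L, qend = L)
          } else {
            out[[length(out) + 1L]] <- data.frame(
              qname = tbl$qname[i], chrom = tbl$chrom[i],
              anchor = rpos - 1L, kind = "right-clip",
              segment = substr(seq, qpos, qpos + L - 1L),
              segmentLen = L, row = i, qstart = qpos,
              qend = qpos + L - 1L)
          }
        }
        if (op == "S") qpos <- qpos + L
      } else if (op == "I") {
        if (L >= minInsertion) {
          out[[length(out) + 1L]] <- data.frame(
            qname = tbl$qname[i], chrom = tbl$chrom[i],
            anchor = rpos - 1L, kind = "internal-insertion",
            segment = substr(seq, qpos, qpos + L - 1L),
            segmentLen = L, row = i, qstart = qpos,
            qend = qpos + L - 1L)
        }
        qpos <- qpos + L
      } else if (op %in% c("M", "=", "X")) {
        qpos <- qpos + L; rpos <- rpos + L
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(qname = character(0), chrom = character(0),
               anchor = integer(0), kind = character(0),
               segment = character(0), segmentLen = integer(0),
               row = integer(0), qstart = integer(0), qend = integer(0))
  attr(res, "skippedNoSeq") <- skipped
  res
}

## Junction-local read subsequences for assembly: the clipped/inserted
## segment plus up to `context` bp of aligned read sequence on each
## available side. Keeps local assembly quadratic in the insertion size
## rather than the read length.
localAssemblyReads <- function(tbl, events, context = 1500L) {
  vapply(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    seq <- tbl$seq[ev$row]
    from <- max(1L, ev$qstart - context)
    to <- min(nchar(seq), ev$qend + context)
    substr(seq, from, to)
  }, "")
}

#' Group clip events into candidate sites
#'
#' Single-linkage grouping of event anchors within \code{window} bp; a
#' group is rejected when the RMS distance of anchors from the median
#' anchor (the dispersion) exceeds \code{maxDispersion}. The median
#' anchor becomes the candidate site.
#'
#' @param events From \code{\link{harvestBreakpointEvidence}}.
#' @param window Grouping distance (default 75 bp).
#' @param maxDispersion Dispersion gate (default 45 bp).
#' @return List of accepted groups: \code{chrom}, \code{medianSite},
#'   \code{dispersion}, \code{eventIdx} (rows of \code{events}),
#'   \code{size}. Rejected-group count in \code{attr(, "rejected")}.
#' @export
groupClipEvents <- function(events, window = 75L, maxDispersion = 45L) {
  out <- list(); rejected <- 0L
  if (nrow(events)) {
    for (chrom in unique(events$chrom)) {
      idx <- which(events$chrom == chrom)
      cid <- gapCluster(events$anchor[idx], window)
      for (k in unique(cid)) {
        ei <- idx[cid == k]
        anchors <- events$anchor[ei]
        med <- as.integer(round(stats::median(anchors)))
        disp <- sqrt(mean((anchors - med)^2))
        if (disp > maxDispersion) { rejected <- rejected + 1L; next }
        out[[length(out) + 1L]] <- list(chrom = chrom, medianSite = med,
                                        dispersion = disp, eventIdx = ei,
                                        size = length(ei))
      }
    }
  }
  attr(out, "rejected") <- rejected
  out
}

#' Built-in local assembler (backbone and polish)
#'
#' The longest read is the backbone; remaining reads are aligned to the
#' growing contig, extend it when their overhang reaches past either end,
#' and finally vote per column so the consensus corrects substitution
#' errors. Deterministic: reads are processed in (length, sequence) order,
#' so the result is invariant to input permutation. An external assembler
#' can be substituted behind the same contract.
#'
#' @param reads Character vector (or \code{DNAStringSet}) of read
#'   sequences.
#' @param seed Unused by the built-in assembler (kept for the contract).
#' @param minOverlap,minIdentity Overlap acceptance (default 200 bp, 70).
#' @param maxReads Use at most this many reads (longest first; default
#'   5) -- deep clusters carry redundant evidence.
#' @param maxPolishCells Dynamic-programming budget for the polish step;
#'   reads are subsampled (longest first) to stay within it.
#' @return list(contig, nReads, nAligned, failed). \code{failed} is TRUE
#'   when fewer than half of the non-backbone reads align to the backbone
#'   (mutually unalignable read sets).
#' @export
assembleLocal <- function(reads, seed = 1L, minOverlap = 200L,
                          minIdentity = 70, maxReads = 5L,
                          maxPolishCells = 4e8) {
  reads <- as.character(reads)
  reads <- reads[!is.na(reads) & nchar(reads) > 0]
  n <- length(reads)
  stopifnot(n >= 1L)
  o <- order(-nchar(reads), reads)
  reads <- reads[o]
  if (n > maxReads) { reads <- reads[seq_len(maxReads)]; n <- maxReads }
  contig <- reads[1L]
  if (n == 1L)
    return(list(contig = contig, nReads = 1L, nAligned = 1L, failed = FALSE))
  rest <- reads[-1L]
  doAlign <- function(r, ctg) {
    Biostrings::pairwiseAlignment(DNAString(r), DNAString(ctg),
                                  type = "local",
                                  substitutionMatrix = .alnMat(),
                                  gapOpening = 4, gapExtension = 2)
  }
  metrics <- function(pa) {
    alnLen <- nchar(pa)
    list(score = Biostrings::score(pa),
         qstart = Biostrings::start(Biostrings::pattern(pa)),
         qend = Biostrings::end(Biostrings::pattern(pa)),
         tstart = Biostrings::start(Biostrings::subject(pa)),
         tend = Biostrings::end(Biostrings::subject(pa)),
         identity = if (alnLen > 0)
           100 * Biostrings::nmatch(pa) / alnLen else 0,
         alnLen = alnLen)
  }
  aligned <- character(0)
  pas <- list()           # first-pass alignments, reusable for polish
  extended <- FALSE
  remaining <- rest
  for (pass in 1:4) {
    progress <- FALSE
    still <- character(0)
    for (r in remaining) {
      minOv <- min(minOverlap, nchar(r) %/% 2L)
      pa <- doAlign(r, contig); a <- metrics(pa)
      if (a$alnLen < minOv || a$identity < minIdentity) {
        r2 <- revComp(r)
        pa2 <- doAlign(r2, contig); a2 <- metrics(pa2)
        if (a2$alnLen < minOv || a2$identity < minIdentity) {
          still <- c(still, r)
          next
        }
        r <- r2; pa <- pa2; a <- a2
      }
      if (a$tstart <= 20L && a$qstart > 20L) {       # extend left
        contig <- paste0(substr(r, 1L, a$qstart - 1L), contig)
        extended <- TRUE
      }
      if (a$tend >= nchar(contig) - 20L && a$qend < nchar(r) - 20L) {
        contig <- paste0(contig, substr(r, a$qend + 1L, nchar(r)))
        extended <- TRUE
      }
      aligned <- c(aligned, r)
      pas[[length(pas) + 1L]] <- pa
      progress <- TRUE
    }
    remaining <- still
    if (!progress || !length(remaining)) break
  }
  nAligned <- length(aligned) + 1L
  failed <- length(aligned) < ceiling(length(rest) / 2)
  if (failed)
    return(list(contig = contig, nReads = n, nAligned = nAligned,
                failed = TRUE))
  ## polish by per-column majority vote (substitutions only); phase-1
  ## alignments are reused unless the contig grew, in which case the
  ## aligned reads are re-aligned to the final contig under a DP budget
  cl <- nchar(contig)
  if (extended && length(aligned)) {
    budget <- cumsum(as.numeric(nchar(aligned)) * cl)
    keep <- budget <= maxPolishCells
    pas <- lapply(aligned[keep], doAlign, ctg = contig)
  }
  if (length(pas)) {
    ctgChars <- strsplit(contig, "", fixed = TRUE)[[1L]]
    votes <- matrix(0L, nrow = 5L, ncol = cl,
                    dimnames = list(c("A", "C", "G", "T", "N"), NULL))
    base <- match(ctgChars, rownames(votes))
    votes[cbind(base, seq_len(cl))] <- 1L   # backbone's own vote
    for (pa in pas) {
      p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
      s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
      tpos <- Biostrings::start(Biostrings::subject(pa))
      ins <- s == "-"
      p <- p[!ins]
      bi <- match(p, rownames(votes))
      pos <- tpos + seq_along(p) - 1L
      okv <- !is.na(bi) & pos <= cl
      votes[cbind(bi[okv], pos[okv])] <- votes[cbind(bi[okv], pos[okv])] + 1L
    }
    winner <- apply(votes, 2L, which.max)
    contig <- paste(rownames(votes)[winner], collapse = "")
  }
  list(contig = contig, nReads = n, nAligned = nAligned, failed = FALSE)
}

#' Extract the insertion sequence from an assembled contig
#'
#' The 5' and 3' reference flanks of the candidate site are aligned to the
#' contig (both contig orientations tried); when both align well
#' (identity >= 80 over >= 80\% of the flank) and are separated by at
#' least \code{minGap} bp, the contig sequence strictly between the two
#' flank hits is the insertion, and the inner flank edges refine the
#' reference breakpoints (replacing the cluster median site).
#'
#' @param contig Assembled contig sequence.
#' @param refSeq Reference chromosome sequence.
#' @param site Candidate site (1-based; cluster median).
#' @param flankLen Flank length (default 500 bp).
#' @param minGap Minimum contig gap to call an insertion (default 50 bp).
#' @param minFlankIdentity,minFlankCoverage Flank acceptance (80, 0.8).
#' @return list(contig, insertionSeq, refinedLeftBp, refinedRightBp,
#'   flipped), or NULL when a flank does not align (unresolved) or the
#'   flank hits are contiguous (no insertion).
#' @export
extractInsertion <- function(contig, refSeq, site, flankLen = 500L,
                             minGap = 50L, minFlankIdentity = 80,
                             minFlankCoverage = 0.8) {
  refSeq <- DNAString(as.character(refSeq))
  fL <- as.character(Biostrings::subseq(refSeq, max(1L, site - flankLen + 1L),
                                        site))
  fRend <- min(length(refSeq), site + flankLen)
  fR <- as.character(Biostrings::subseq(refSeq, site + 1L, fRend))
  tryOne <- function(ctg, flipped) {
    aL <- alignPair(fL, ctg, mode = "local")
    aR <- alignPair(fR, ctg, mode = "local")
    okL <- aL$identity >= minFlankIdentity &&
      aL$alnLen >= minFlankCoverage * nchar(fL) && aL$orientation == "+"
    okR <- aR$identity >= minFlankIdentity &&
      aR$alnLen >= minFlankCoverage * nchar(fR) && aR$orientation == "+"
    if (!okL || !okR) return(structure(list(), reason = "unresolved"))
    if (aR$tstart <= aL$tend) return(structure(list(), reason = "no_insertion"))
    gap <- aR$tstart - aL$tend - 1L
    if (gap < minGap) return(structure(list(), reason = "no_insertion"))
    list(contig = ctg,
         insertionSeq = substr(ctg, aL$tend + 1L, aR$tstart - 1L),
         refinedLeftBp = site - (nchar(fL) - aL$qend),
         refinedRightBp = site + aR$qstart - 1L,
         flipped = flipped)
  }
  res <- tryOne(contig, FALSE)
  if (!length(res)) {
    res2 <- tryOne(revComp(contig), TRUE)
    if (length(res2)) return(res2)
    return(NULL)
  }
  res
}

#' Annotate the TE family of an insertion sequence
#'
#' \code{\link{classifySequence}} verdict plus the residual (unaligned)
#' terminal segments, which feed transduction tracing and the pseudogene
#' scan downstream.
#'
#' @param insertionSeq Insertion sequence (>= 50 bp).
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param minResidual Minimum residual segment length kept (default 50).
#' @return list(family, subfamily, identityPct, queryCoveragePct,
#'   orientation, residuals = character vector). Family is "unknown" when
#'   nothing in the library matches.
#' @export
annotateTeFamily <- function(insertionSeq, library, minResidual = 50L) {
  stopifnot(nchar(insertionSeq) >= 50L)
  hit <- classifySequence(insertionSeq, library)
  if (is.null(hit)) {
    return(list(family = "unknown", subfamily = NA_character_,
                identityPct = NA_real_, queryCoveragePct = NA_real_,
                orientation = NA_character_, residuals = insertionSeq))
  }
  res <- character(0)
  if (hit$qstart - 1L >= minResidual)
    res <- c(res, substr(insertionSeq, 1L, hit$qstart - 1L))
  if (nchar(insertionSeq) - hit$qend >= minResidual)
    res <- c(res, substr(insertionSeq, hit$qend + 1L, nchar(insertionSeq)))
  c(hit[c("family", "subfamily", "identityPct", "queryCoveragePct",
          "orientation")], list(residuals = res))
}

#' Trace the transduction source of a residual segment (long reads)
#'
#' The residual is aligned to the indexed 3'-flank windows of all
#' full-length source elements; a canonical transduction is reported only
#' when exactly one window matches uniquely at >= 90\% identity.
#'
#' @param residual Residual sequence (>= 50 bp).
#' @param library \code{\link{ConsensusLibrary}} with a flank index.
#' @param minIdentity,minLen Hit acceptance (default 90, 50).
#' @return list(kind, srcChrom, srcStart, srcEnd, transducedLen).
#' @export
traceTransductionLr <- function(residual, library, minIdentity = 90,
                                minLen = 50L) {
  none <- list(kind = "none", srcChrom = NA_character_,
               srcStart = NA_integer_, srcEnd = NA_integer_,
               transducedLen = 0L)
  if (is.na(residual) || nchar(residual) < minLen) return(none)
  fi <- flankIndex(library); fs <- flankSeqs(library)
  if (!length(fi)) return(none)
  scores <- numeric(length(fi)); qual <- logical(length(fi))
  hits <- vector("list", length(fi))
  for (w in seq_along(fi)) {
    a <- alignPair(residual, fs[[w]], mode = "local")
    scores[w] <- a$score
    qual[w] <- a$identity >= minIdentity && a$alnLen >= minLen
    hits[[w]] <- a
  }
  if (!any(qual)) return(none)
  best <- which.max(ifelse(qual, scores, -Inf))
  others <- scores[-best]
  if (length(others) && max(others) >= 0.9 * scores[best]) return(none)
  list(kind = "canonical",
       srcChrom = as.character(seqnames(fi)[best]),
       srcStart = start(fi)[best], srcEnd = end(fi)[best],
       transducedLen = hits[[best]]$alnLen)
}

#' Merge short-read and long-read candidates
#'
#' Calls within \code{mergeWindow} bp are merged, keeping the long-read
#' breakpoints and insertion sequence (the assembled evidence) and
#' setting provenance to hybrid; unmatched calls are carried over.
#'
#' @param shortCalls,longCalls \code{\link{InsertionCallSet}} objects.
#' @param mergeWindow Default 50 bp.
#' @return An \code{\link{InsertionCallSet}}.
#' @export
mergeHybridCandidates <- function(shortCalls, longCalls, mergeWindow = 50L) {
  sg <- insertionCalls(shortCalls)
  lg <- insertionCalls(longCalls)
  if (!length(sg)) return(longCalls)
  if (!length(lg)) return(shortCalls)
  ov <- GenomicRanges::findOverlaps(sg, lg, maxgap = mergeWindow)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  keepFirst <- !duplicated(sh)
  qh <- qh[keepFirst]; sh <- sh[keepFirst]
  merged <- lg
  if (length(sh)) {
    mcols(merged)$provenance[sh] <- "hybrid"
    ## carry short-read-only mechanistic evidence where the long call
    ## lacks it
    for (col in c("tsdSeq", "tsdLen")) {
      empty <- mcols(merged)[[col]][sh] %in% c("", 0L)
      mcols(merged)[[col]][sh[empty]] <- mcols(sg)[[col]][qh[empty]]
    }
  }
  soloShort <- sg[setdiff(seq_along(sg), qh)]
  InsertionCallSet(c(merged, soloShort))
}

#' Call nonreference TE insertions from long-read alignments
#'
#' Pipeline: evidence harvest, clip grouping (75 bp window, 45 bp
#' dispersion gate), local assembly, flank-guided insertion extraction
#' with breakpoint refinement, family annotation, and transduction
#' tracing. Deterministic and shard-invariant.
#'
#' @param tbl Coordinate-sorted long-read alignment table.
#' @param reference Named \code{DNAStringSet} or single sequence.
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param window,maxDispersion Grouping parameters (75, 45).
#' @param minClip,minInsertion Evidence thresholds (30, 100).
#' @param minSupport Minimum reads per group (default 2).
#' @return An \code{\link{InsertionCallSet}} (assembled insertion
#'   sequences in the \code{insSeq} column); assembly-failure count in
#'   \code{attr(insertionCalls(x), "assemblyFailures")} is reported via
#'   message.
#' @export
callInsertionsLong <- function(tbl, reference, library, window = 75L,
                               maxDispersion = 45L, minClip = 30L,
                               minInsertion = 100L, minSupport = 2L) {
  events <- harvestBreakpointEvidence(tbl, minClip, minInsertion)
  groups <- groupClipEvents(events, window, maxDispersion)
  calls <- list(); failures <- 0L
  for (g in groups) {
    if (g$size < minSupport) next
    refSeq <- if (is(reference, "DNAStringSet")) reference[[g$chrom]]
              else reference
    ge <- events[g$eventIdx, , drop = FALSE]
    ge <- ge[!duplicated(ge$qname), , drop = FALSE]
    reads <- localAssemblyReads(tbl, ge)
    asm <- assembleLocal(reads)
    if (asm$failed) { failures <- failures + 1L; next }
    ext <- extractInsertion(asm$contig, refSeq, g$medianSite)
    if (is.null(ext) || !length(ext)) next
    ann <- annotateTeFamily(ext$insertionSeq, library)
    td <- list(kind = "none", srcChrom = NA_character_,
               srcStart = NA_integer_, srcEnd = NA_integer_,
               transducedLen = 0L)
    for (r in ann$residuals) {
      t <- traceTransductionLr(r, library)
      if (t$kind != "none") { td <- t; break }
    }
    pa <- polyASignal(ext$insertionSeq)
    tsdLen <- max(0L, ext$refinedLeftBp - ext$refinedRightBp)
    gr <- GRanges(g$chrom, IRanges(ext$refinedLeftBp, width = 1L))
    mcols(gr) <- DataFrame(
      family = ann$family, subfamily = ann$subfamily,
      leftBp = min(ext$refinedLeftBp, ext$refinedRightBp),
      rightBp = max(ext$refinedLeftBp, ext$refinedRightBp),
      orientation = if (is.na(ann$orientation)) "+" else ann$orientation,
      tsdSeq = "", tsdLen = tsdLen,
      polyALen = pa$len, polyASide = pa$side,
      tdKind = td$kind, tdChrom = td$srcChrom,
      tdStart = td$srcStart, tdEnd = td$srcEnd,
      clipLeft = g$size, clipRight = 0L, disc = 0L, spanning = 0L,
      tsdelStart = NA_integer_, tsdelEnd = NA_integer_,
      genotype = NA_character_, gq = NA_real_,
      provenance = "long", insSeq = ext$insertionSeq)
    calls[[length(calls) + 1L]] <- gr
  }
  if (failures > 0L)
    message(failures, " candidate group(s) dropped: local assembly failed")
  if (!length(calls)) return(InsertionCallSet())
  InsertionCallSet(do.call(c, calls))
}
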