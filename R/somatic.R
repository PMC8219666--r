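## Case/control somatic TE-insertion calling.

#' Classify case calls as somatic or germline against a matched control
#'
#' For each case call the control sample is scanned for supporting clipped
#' reads within +/- 10 bp of the breakpoints and discordant pairs over the
#' site. A call is somatic when clips + discordant support is at most the
#' depth-scaled allowance \code{max(1, floor(controlDepth / 30))},
#' germline when support exceeds three times the allowance, and ambiguous
#' in between or when the control has < 5X coverage at the site.
#'
#' @param caseCalls An \code{\link{InsertionCallSet}} from the case sample.
#' @param controlTbl Coordinate-sorted control alignment table.
#' @param statsControl \code{\link{LibraryStats}} of the control.
#' @param clipWindow Breakpoint tolerance (default 10 bp).
#' @return data.frame, one row per case call: control support counts,
#'   control depth at the site and \code{status} in
#'   \{somatic, germline, ambiguous\} (+ \code{lowCoverage} flag).
#' @export
callSomatic <- function(caseCalls, controlTbl, statsControl,
                        clipWindow = 10L) {
  gr <- insertionCalls(caseCalls)
  mc <- mcols(gr)
  out <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                    controlClip = 0L, controlDisc = 0L,
                    controlDepth = 0, status = "ambiguous",
                    lowCoverage = FALSE)
  if (!length(gr)) return(out)
  for (i in seq_along(gr)) {
    chrom <- out$chrom[i]
    lbp <- mc$leftBp[i]; rbp <- mc$rightBp[i]
    if (is.na(rbp)) rbp <- lbp
    use <- controlTbl$isMapped & !controlTbl$isSupp & !controlTbl$isDup &
      controlTbl$chrom == chrom
    near <- use & controlTbl$pos <= rbp + 1000L &
      controlTbl$endpos >= lbp - 1000L
    sub <- controlTbl[near, , drop = FALSE]
    clips <- sum((sub$clipR >= 10L & abs(sub$endpos - rbp) <= clipWindow) |
                   (sub$clipL >= 10L & abs((sub$pos - 1L) - lbp) <= clipWindow))
    disc <- sum(!sub$isProper & sub$pos <= rbp + 600L &
                  sub$endpos >= lbp - 600L)
    dwin <- 200L
    depth <- sum(sub$pos <= rbp + dwin & sub$endpos >= lbp - dwin) *
      readLength(statsControl) /
      (rbp - lbp + 2 * dwin + readLength(statsControl))
    out$controlClip[i] <- clips
    out$controlDisc[i] <- disc
    out$controlDepth[i] <- depth
    if (depth < 5) {
      out$status[i] <- "ambiguous"; out$lowCoverage[i] <- TRUE
      next
    }
    allowance <- max(1L, as.integer(floor(depth / 30)))
    support <- clips + disc
    out$status[i] <- if (support <= allowance) "somatic"
                     else if (support > 3L * allowance) "germline"
                     else "ambiguous"
  }
  out
}

#' Re-scan a case sample with clonality-scaled thresholds
#'
#' Re-runs short-read calling with thresholds from
#' \code{autoThresholds(stats, clonality)}; lowering clonality lowers the
#' support minima, so on fixed data the call set at clonality 1 is a
#' subset of the call set at any clonality < 1.
#'
#' @param tbl Case alignment table.
#' @param reference,library,annotations As for
#'   \code{\link{callInsertionsShort}}.
#' @param clonality Expected cell fraction in (0, 1].
#' @param stats Optional precomputed \code{\link{LibraryStats}}.
#' @return An \code{\link{InsertionCallSet}}.
#' @export
rescanLowClonality <- function(tbl, reference, library, annotations = NULL,
                               clonality = 1, stats = NULL) {
  stopifnot(clonality > 0, clonality <= 1)
  if (is.null(stats)) stats <- estimateLibraryStats(tbl)
  thr <- autoThresholds(stats, clonality)
  callInsertionsShort(tbl, reference, library, annotations,
                      thresholds = thr, stats = stats)
}
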