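## Library statistics and depth-scaled calling thresholds.

#' Estimate insert-size, read-length and depth statistics
#'
#' Moments are computed from up to \code{sampleSize} properly paired
#' fragments after discarding insert sizes beyond the 99.5th percentile;
#' depth is read count x read length / sampled window span. Deterministic
#' for a fixed stream (the first \code{sampleSize} pairs are used).
#'
#' @param tbl Alignment table (coordinate-sorted short reads).
#' @param sampleSize Maximum number of proper pairs used (default 100000).
#' @return A \code{\link{LibraryStats}}.
#' @export
estimateLibraryStats <- function(tbl, sampleSize = 100000L) {
  checkSorted(tbl)
  sel <- tbl$isMapped & tbl$isProper & !tbl$isSupp & !tbl$isDup &
    !is.na(tbl$tlen) & tbl$tlen > 0L
  ins <- tbl$tlen[sel]
  if (length(ins) > sampleSize) ins <- ins[seq_len(sampleSize)]
  if (length(ins) < 100L)
    stop("insufficient data: fewer than 100 proper pairs")
  cut <- stats::quantile(ins, 0.995, names = FALSE, type = 1)
  ins <- ins[ins <= cut]
  mapped <- tbl$isMapped & !tbl$isSupp
  rl <- cigarWidthAlongQuerySpace(tbl$cigar[mapped][1:min(1000L, sum(mapped))])
  readLen <- modalValue(rl)
  span <- sum(vapply(split(seq_len(nrow(tbl))[mapped], tbl$chrom[mapped]),
                     function(i) {
                       max(tbl$endpos[i]) - min(tbl$pos[i]) + 1L
                     }, 0L))
  depth <- sum(mapped) * readLen / span
  LibraryStats(meanInsert = mean(ins), sdInsert = stats::sd(ins),
               readLength = readLen, meanDepth = depth)
}

#' Thresholds for insertion calling
#'
#' Minimum clip-read and discordant-read support, scaled with sequencing
#' depth and (for somatic mode) the expected clonality:
#' \code{max(2, floor(depth * clonality / 10))} for both minima.
#'
#' @param stats A \code{\link{LibraryStats}}.
#' @param clonality Expected cell fraction carrying the insertions, in
#'   (0, 1]; 1 for germline calling.
#' @param maxRefDivergencePct Divergence-filter threshold carried along
#'   (default 5).
#' @return A list with \code{minClipReads}, \code{minDiscReads},
#'   \code{maxRefDivergencePct}, \code{clonality}.
#' @export
autoThresholds <- function(stats, clonality = 1, maxRefDivergencePct = 5) {
  stopifnot(clonality > 0, clonality <= 1)
  m <- max(2L, as.integer(floor(meanDepth(stats) * clonality / 10)))
  list(minClipReads = m, minDiscReads = m,
       maxRefDivergencePct = maxRefDivergencePct, clonality = clonality)
}
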