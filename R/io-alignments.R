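## Alignment tables.
##
## All callers operate on a plain data.frame with one row per alignment
## record and SAM-like columns (qname, flag, chrom, pos, mapq, cigar,
## mchrom, mpos, tlen, seq) plus derived convenience columns. Tables come
## either from a coordinate-sorted BAM/SAM/CRAM through Rsamtools or
## directly from the bundled simulator.

#' @importFrom GenomicAlignments explodeCigarOps explodeCigarOpLengths
#'   cigarWidthAlongReferenceSpace cigarWidthAlongQuerySpace
NULL

## SAM flag helpers
flagBit <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Build (or complete) an alignment table
#'
#' Adds the derived columns the callers rely on: \code{refWidth},
#' \code{endpos} (1-based inclusive end on the reference), clip lengths
#' \code{clipL}/\code{clipR}, and logical flag columns \code{isMapped},
#' \code{isProper}, \code{isDup}, \code{isSupp}, \code{isReverse},
#' \code{isFirst}.
#'
#' @param df data.frame with at least \code{qname}, \code{flag},
#'   \code{chrom}, \code{pos} (1-based), \code{mapq}, \code{cigar},
#'   \code{mchrom}, \code{mpos}, \code{tlen}, \code{seq} (\code{NA} or
#'   \code{"*"} when the sequence is not stored).
#' @return The completed data.frame.
#' @export
alignmentTable <- function(df) {
  need <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
            "mchrom", "mpos", "tlen", "seq")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("alignment table lacks columns: ", paste(missing, collapse = ", "))
  df$flag <- as.integer(df$flag)
  df$pos <- as.integer(df$pos)
  df$isMapped <- !flagBit(df$flag, 4L)
  df$isProper <- flagBit(df$flag, 2L)
  df$isDup <- flagBit(df$flag, 1024L)
  df$isSupp <- flagBit(df$flag, 2048L)
  df$isReverse <- flagBit(df$flag, 16L)
  df$isFirst <- flagBit(df$flag, 64L)
  df$refWidth <- 0L
  ok <- df$isMapped & !is.na(df$cigar) & df$cigar != "*"
  if (any(ok))
    df$refWidth[ok] <- cigarWidthAlongReferenceSpace(df$cigar[ok])
  df$endpos <- df$pos + df$refWidth - 1L
  df$clipL <- 0L; df$clipR <- 0L
  cl <- regmatches(df$cigar, regexpr("^[0-9]+[SH]", df$cigar))
  has <- ok & grepl("^[0-9]+[SH]", df$cigar)
  df$clipL[has] <- as.integer(sub("[SH]", "", regmatches(
    df$cigar[has], regexpr("^[0-9]+[SH]", df$cigar[has]))))
  hasR <- ok & grepl("[0-9]+[SH]$", df$cigar)
  df$clipR[hasR] <- as.integer(sub("[SH]", "", regmatches(
    df$cigar[hasR], regexpr("[0-9]+[SH]$", df$cigar[hasR]))))
  df
}

#' Read a coordinate-sorted BAM/SAM/CRAM into an alignment table
#'
#' @param path BAM (indexed or not), SAM, or CRAM file. SAM is converted
#'   through \code{Rsamtools::asBam}; CRAM is resolved through the same
#'   reader contract.
#' @param region Optional \code{GRanges} restricting the fetch.
#' @return An alignment table (see \code{\link{alignmentTable}}).
#' @export
readAlignments <- function(path, region = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what)
  } else Rsamtools::ScanBamParam(what = what, which = region)
  res <- Rsamtools::scanBam(path, param = param)
  dfs <- lapply(res, function(x) {
    data.frame(qname = x$qname, flag = x$flag,
               chrom = as.character(x$rname), pos = x$pos,
               mapq = x$mapq, cigar = x$cigar,
               mchrom = as.character(x$mrnm), mpos = x$mpos,
               tlen = x$isize, seq = as.character(x$seq))
  })
  df <- do.call(rbind, dfs)
  df$pos[is.na(df$pos)] <- 0L
  alignmentTable(df)
}

#' Write an alignment table as SAM
#'
#' @param tbl Alignment table.
#' @param refLens Named integer vector of reference sequence lengths.
#' @param path Output path (\code{.sam}).
#' @export
writeSam <- function(tbl, refLens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refLens), as.integer(refLens)))
  o <- order(match(tbl$chrom, names(refLens)), tbl$pos)
  tbl <- tbl[o, ]
  seqs <- ifelse(is.na(tbl$seq) | tbl$seq == "", "*", tbl$seq)
  mch <- ifelse(is.na(tbl$mchrom), "*",
                ifelse(tbl$mchrom == tbl$chrom, "=", tbl$mchrom))
  rows <- paste(tbl$qname, tbl$flag,
                ifelse(is.na(tbl$chrom), "*", tbl$chrom),
                pmax(tbl$pos, 0L), tbl$mapq,
                ifelse(is.na(tbl$cigar), "*", tbl$cigar),
                mch, pmax(ifelse(is.na(tbl$mpos), 0L, tbl$mpos), 0L),
                ifelse(is.na(tbl$tlen), 0L, tbl$tlen),
                seqs, "*", sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## Leading/trailing soft-clipped substrings of a record's stored sequence.
clipSeq <- function(seq, clipL, clipR, side) {
  if (is.na(seq) || seq == "" || seq == "*") return(NA_character_)
  n <- nchar(seq)
  if (side == "left") {
    if (clipL <= 0L) NA_character_ else substr(seq, 1L, clipL)
  } else {
    if (clipR <= 0L) NA_character_ else substr(seq, n - clipR + 1L, n)
  }
}

## Per-base coverage of mapped reads over [from, to] on one chromosome.
coverageTrack <- function(tbl, chrom, from, to) {
  sel <- tbl$isMapped & !tbl$isSupp & tbl$chrom == chrom &
    tbl$endpos >= from & tbl$pos <= to
  cov <- integer(to - from + 1L)
  if (any(sel)) {
    s <- pmax(tbl$pos[sel], from) - from + 1L
    e <- pmin(tbl$endpos[sel], to) - from + 1L
    for (i in seq_along(s)) cov[s[i]:e[i]] <- cov[s[i]:e[i]] + 1L
  }
  cov
}

## Assert that an alignment table is coordinate-sorted within chromosomes.
checkSorted <- function(tbl) {
  sp <- split(tbl$pos[tbl$isMapped], tbl$chrom[tbl$isMapped])
  ok <- all(vapply(sp, function(p) !is.unsorted(p), TRUE))
  if (!ok) stop("alignments are not coordinate-sorted")
  invisible(TRUE)
}
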