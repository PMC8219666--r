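## RepeatMasker .out reading/writing.
##
## The standard .out layout: 3 header lines then whitespace-separated
## columns (score, div, del, ins, query, qbegin, qend, qleft, strand,
## repeat, class/family, rbegin, rend, rleft, id), 1-based inclusive
## query coordinates. The family label is taken as the component after
## the "/" of the class/family column (or the whole column if none).

#' Parse a RepeatMasker .out file
#'
#' @param path Path to a .out file.
#' @return A \code{GRanges} (1-based inclusive, as in the file) with
#'   metadata columns \code{family}, \code{subfamily}, \code{divergencePct},
#'   \code{isFullLength} (\code{NA} until \code{\link{annotateFullLength}}).
#' @export
parseRepeatmaskerOut <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(family = character(0), subfamily = character(0),
                           divergencePct = numeric(0), isFullLength = logical(0))
    return(gr)
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n <- vapply(fields, length, 0L)
  bad <- which(n < 13L)
  if (length(bad))
    stop(sprintf("malformed RepeatMasker row at line %d: %s",
                 bad[1] + 3L, lines[bad[1]]))
  f <- function(i) vapply(fields, `[[`, "", i)
  div <- suppressWarnings(as.numeric(f(2)))
  qbeg <- suppressWarnings(as.integer(f(6)))
  qend <- suppressWarnings(as.integer(f(7)))
  badnum <- which(is.na(div) | is.na(qbeg) | is.na(qend))
  if (length(badnum))
    stop(sprintf("malformed RepeatMasker row at line %d: %s",
                 badnum[1] + 3L, lines[badnum[1]]))
  classfam <- f(11)
  fam <- sub("^.*/", "", classfam)
  strand <- ifelse(f(9) == "C", "-", "+")
  gr <- GRanges(f(5), IRanges(qbeg, qend), strand = strand)
  mcols(gr) <- DataFrame(family = fam, subfamily = f(10),
                         divergencePct = div,
                         isFullLength = rep(NA, length(gr)))
  gr
}

#' Write repeat annotations as a RepeatMasker .out file
#'
#' Inverse of \code{\link{parseRepeatmaskerOut}}; coordinates are written
#' 1-based inclusive so a read/write round trip preserves them exactly.
#'
#' @param gr \code{GRanges} with \code{family}, \code{subfamily},
#'   \code{divergencePct} metadata.
#' @param path Output path.
#' @param classPrefix Named character giving the class component written
#'   before the family (default guesses from the family label).
#' @export
writeRepeatmaskerOut <- function(gr, path, classPrefix = NULL) {
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin  end          (left)  repeat         class/family      begin   end    (left)   ID",
    "")
  guessClass <- function(fam) {
    if (!is.null(classPrefix) && fam %in% names(classPrefix))
      return(classPrefix[[fam]])
    switch(fam,
           L1 = "LINE/L1", Alu = "SINE/Alu", SVA = "Retroposon/SVA",
           LTR = "LTR/LTR", HERV = "LTR/HERV",
           Alpha = "Satellite/Alpha", Beta = "Satellite/Beta",
           HSATII = "Satellite/HSATII",
           paste0("Unknown/", fam))
  }
  mc <- mcols(gr)
  rows <- vapply(seq_along(gr), function(i) {
    sprintf("%5d %6.1f  0.0  0.0  %-10s %7d %7d (%d) %s %-14s %-17s %6d %6d (0) %6d",
            1000L, mc$divergencePct[i], as.character(seqnames(gr)[i]),
            start(gr)[i], end(gr)[i], 0L,
            ifelse(as.character(strand(gr)[i]) == "-", "C", "+"),
            mc$subfamily[i], guessClass(mc$family[i]),
            1L, width(gr)[i], i)
  }, "")
  writeLines(c(hdr, rows), path)
}

#' Flag repeat annotations that are full length relative to the consensus
#'
#' @param gr Repeat annotations (\code{GRanges} from
#'   \code{\link{parseRepeatmaskerOut}}).
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param minFraction Minimum fraction of the consensus length (default 0.95).
#' @return \code{gr} with \code{isFullLength} filled in (\code{NA} for
#'   subfamilies absent from the library).
#' @export
annotateFullLength <- function(gr, library, minFraction = 0.95) {
  lens <- Biostrings::width(consensusSeqs(library))
  names(lens) <- names(consensusSeqs(library))
  cl <- lens[mcols(gr)$subfamily]
  mcols(gr)$isFullLength <- ifelse(is.na(cl), NA, width(gr) >= minFraction * cl)
  gr
}

#' Read a BED12 exon annotation into an exon index
#'
#' One BED12 row per transcript; block fields give the exon structure.
#'
#' @param path BED12 file path.
#' @param reference Named \code{DNAStringSet} (or single \code{DNAString})
#'   giving the reference sequence, used to extract exon sequences.
#' @return A data.frame with one row per exon: \code{gene}, \code{exon}
#'   (1-based index along the transcript), \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), \code{seq}.
#' @export
readExonsBed <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12) stop("BED12 row with fewer than 12 fields")
    chrom <- f[1]; chromStart <- as.integer(f[2]); gene <- f[4]
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1L]])
    starts <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1L]])
    for (k in seq_along(sizes)) {
      s <- chromStart + starts[k] + 1L          # BED 0-based -> 1-based
      e <- s + sizes[k] - 1L
      refseq <- if (is(reference, "DNAStringSet")) reference[[chrom]] else reference
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, exon = k, chrom = chrom, start = s, end = e,
        seq = as.character(Biostrings::subseq(refseq, s, e)))
    }
  }
  do.call(rbind, out)
}

#' Write transcripts as BED12
#'
#' @param transcripts data.frame with \code{chrom}, \code{gene},
#'   \code{txStart}, \code{txEnd} (1-based inclusive) and list-columns
#'   \code{exonStarts}/\code{exonEnds} (1-based inclusive per exon).
#' @param path Output path.
#' @export
writeExonsBed <- function(transcripts, path) {
  rows <- vapply(seq_len(nrow(transcripts)), function(i) {
    es <- transcripts$exonStarts[[i]]; ee <- transcripts$exonEnds[[i]]
    sizes <- ee - es + 1L
    offs <- es - transcripts$txStart[i]
    paste(transcripts$chrom[i], transcripts$txStart[i] - 1L,
          transcripts$txEnd[i], transcripts$gene[i], 0L, "+",
          transcripts$txStart[i] - 1L, transcripts$txEnd[i], "0",
          length(es), paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","), sep = "\t")
  }, "")
  writeLines(rows, path)
}
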