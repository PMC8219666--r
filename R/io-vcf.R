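## VCF 4.2 output/input for insertion calls. ALT alleles are symbolic
## mobile-element alleles (<INS:ME:LINE1> etc.); INFO carries the
## subfamily, mechanistic signatures, transduction source and support
## counts; the sample column carries GT and a genotype confidence.

.meAlt <- function(family) {
  map <- c(L1 = "LINE1", Alu = "ALU", SVA = "SVA", HERV = "HERV",
           pseudogene = "PSEUDOGENE")
  tag <- ifelse(is.na(family), "OTHER",
                ifelse(family %in% names(map), map[family], "OTHER"))
  sprintf("<INS:ME:%s>", tag)
}

.vcfInfoDefs <- c(
  '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
  '##INFO=<ID=FAMILY,Number=1,Type=String,Description="TE family">',
  '##INFO=<ID=SUBFAMILY,Number=1,Type=String,Description="TE subfamily">',
  '##INFO=<ID=MESTRAND,Number=1,Type=String,Description="Insertion orientation">',
  '##INFO=<ID=LEFTBP,Number=1,Type=Integer,Description="Left breakpoint (1-based)">',
  '##INFO=<ID=RIGHTBP,Number=1,Type=Integer,Description="Right breakpoint (1-based)">',
  '##INFO=<ID=TSD,Number=1,Type=String,Description="Target site duplication sequence">',
  '##INFO=<ID=TSDLEN,Number=1,Type=Integer,Description="TSD length">',
  '##INFO=<ID=POLYA,Number=1,Type=Integer,Description="PolyA tail length">',
  '##INFO=<ID=POLYASIDE,Number=1,Type=String,Description="PolyA side">',
  '##INFO=<ID=TDKIND,Number=1,Type=String,Description="Transduction kind">',
  '##INFO=<ID=TDSRC,Number=1,Type=String,Description="Transduction source locus">',
  '##INFO=<ID=CLIPL,Number=1,Type=Integer,Description="Left-clip support">',
  '##INFO=<ID=CLIPR,Number=1,Type=Integer,Description="Right-clip support">',
  '##INFO=<ID=DISC,Number=1,Type=Integer,Description="Discordant-pair support">',
  '##INFO=<ID=SPAN,Number=1,Type=Integer,Description="Concordant spanning reads">',
  '##INFO=<ID=TSDEL,Number=1,Type=String,Description="Target-site deletion interval">',
  '##INFO=<ID=PROV,Number=1,Type=String,Description="Call provenance (short/long/hybrid)">',
  '##INFO=<ID=INSSEQ,Number=1,Type=String,Description="Assembled insertion sequence">',
  '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic call">',
  '##INFO=<ID=CTRLCLIP,Number=1,Type=Integer,Description="Control clip support">',
  '##INFO=<ID=CTRLDISC,Number=1,Type=Integer,Description="Control discordant support">')

#' Write insertion calls as VCF 4.2
#'
#' @param callset An \code{\link{InsertionCallSet}} (sorted by chrom, pos).
#' @param refLens Named integer vector of reference lengths.
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @param extraInfo Optional data.frame (one row per call) of extra INFO
#'   fields, e.g. \code{SOMATIC}/\code{CTRLCLIP}/\code{CTRLDISC}.
#' @return \code{path}, invisibly.
#' @export
writeInsertionVcf <- function(callset, refLens, path, sample = "SAMPLE",
                              extraInfo = NULL) {
  gr <- insertionCalls(callset)
  if (length(gr)) {
    chroms <- as.character(seqnames(gr))
    if (!all(chroms %in% names(refLens)))
      stop("call on chromosome absent from the reference: ",
           paste(setdiff(chroms, names(refLens)), collapse = ","))
    o <- order(match(chroms, names(refLens)), start(gr))
    if (is.unsorted(o)) stop("calls must be sorted by (chrom, position)")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=retrofind",
           sprintf("##contig=<ID=%s,length=%d>", names(refLens),
                   as.integer(refLens)),
           '##ALT=<ID=INS:ME:LINE1,Description="LINE1 insertion">',
           '##ALT=<ID=INS:ME:ALU,Description="ALU insertion">',
           '##ALT=<ID=INS:ME:SVA,Description="SVA insertion">',
           '##ALT=<ID=INS:ME:HERV,Description="HERV insertion">',
           '##ALT=<ID=INS:ME:PSEUDOGENE,Description="Processed pseudogene insertion">',
           '##ALT=<ID=INS:ME:OTHER,Description="Other insertion">',
           .vcfInfoDefs,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Float,Description="Genotype confidence">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  if (!length(gr)) { writeLines(hdr, path); return(invisible(path)) }
  mc <- mcols(gr)
  kv <- function(key, val, keep) {
    keep <- rep_len(keep, length(gr))
    out <- paste0(key, "=", rep_len(val, length(gr)))
    out[!keep] <- NA
    out
  }
  infoParts <- cbind(
    kv("SVTYPE", "INS", TRUE),
    kv("FAMILY", mc$family, !is.na(mc$family)),
    kv("SUBFAMILY", mc$subfamily, !is.na(mc$subfamily)),
    kv("MESTRAND", mc$orientation, !is.na(mc$orientation)),
    kv("LEFTBP", mc$leftBp, !is.na(mc$leftBp)),
    kv("RIGHTBP", mc$rightBp, !is.na(mc$rightBp)),
    kv("TSD", mc$tsdSeq, !is.na(mc$tsdSeq) & nzchar(mc$tsdSeq)),
    kv("TSDLEN", mc$tsdLen, TRUE),
    kv("POLYA", mc$polyALen, TRUE),
    kv("POLYASIDE", mc$polyASide, TRUE),
    kv("TDKIND", mc$tdKind, TRUE),
    kv("TDSRC", sprintf("%s:%d-%d", mc$tdChrom, mc$tdStart, mc$tdEnd),
       !is.na(mc$tdChrom)),
    kv("CLIPL", mc$clipLeft, TRUE),
    kv("CLIPR", mc$clipRight, TRUE),
    kv("DISC", mc$disc, TRUE),
    kv("SPAN", mc$spanning, TRUE),
    kv("TSDEL", sprintf("%d-%d", mc$tsdelStart, mc$tsdelEnd),
       !is.na(mc$tsdelStart)),
    kv("PROV", mc$provenance, TRUE),
    kv("INSSEQ", mc$insSeq, !is.na(mc$insSeq)))
  if (!is.null(extraInfo)) {
    for (nm in names(extraInfo)) {
      col <- extraInfo[[nm]]
      if (is.logical(col)) {
        flagCol <- rep(NA_character_, length(gr))
        flagCol[col] <- nm
        infoParts <- cbind(infoParts, flagCol)
      } else infoParts <- cbind(infoParts, kv(nm, col, !is.na(col)))
    }
  }
  info <- apply(infoParts, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
  gt <- ifelse(is.na(mc$genotype), "./.", mc$genotype)
  gq <- ifelse(is.na(mc$gq), ".", sprintf("%.4g", mc$gq))
  rows <- paste(as.character(seqnames(gr)), start(gr),
                sprintf("rf_%d", seq_along(gr)), "N", .meAlt(mc$family),
                ".", "PASS", info, "GT:GQ", paste(gt, gq, sep = ":"),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a retrofind VCF back into an InsertionCallSet
#'
#' Inverse of \code{\link{writeInsertionVcf}} for the fields that writer
#' emits; used for round trips and by downstream modules.
#'
#' @param path VCF path.
#' @return An \code{\link{InsertionCallSet}}.
#' @export
readInsertionVcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(InsertionCallSet())
  f <- strsplit(body, "\t", fixed = TRUE)
  getInfo <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (!length(m)) NA_character_ else sub(paste0("^;?", key, "="), "", m)
  }
  one <- function(x) {
    info <- x[8]
    td <- getInfo(info, "TDSRC")
    tdc <- NA_character_; tds <- NA_integer_; tde <- NA_integer_
    if (!is.na(td)) {
      tdc <- sub(":.*", "", td)
      tds <- as.integer(sub("-.*", "", sub(".*:", "", td)))
      tde <- as.integer(sub(".*-", "", td))
    }
    tsdel <- getInfo(info, "TSDEL")
    gtf <- strsplit(x[10], ":", fixed = TRUE)[[1L]]
    gr <- GRanges(x[1], IRanges(as.integer(x[2]), width = 1L))
    mcols(gr) <- DataFrame(
      family = getInfo(info, "FAMILY"),
      subfamily = getInfo(info, "SUBFAMILY"),
      leftBp = as.integer(getInfo(info, "LEFTBP")),
      rightBp = as.integer(getInfo(info, "RIGHTBP")),
      orientation = getInfo(info, "MESTRAND"),
      tsdSeq = { v <- getInfo(info, "TSD"); if (is.na(v)) "" else v },
      tsdLen = as.integer(getInfo(info, "TSDLEN")),
      polyALen = as.integer(getInfo(info, "POLYA")),
      polyASide = getInfo(info, "POLYASIDE"),
      tdKind = getInfo(info, "TDKIND"),
      tdChrom = tdc, tdStart = tds, tdEnd = tde,
      clipLeft = as.integer(getInfo(info, "CLIPL")),
      clipRight = as.integer(getInfo(info, "CLIPR")),
      disc = as.integer(getInfo(info, "DISC")),
      spanning = as.integer(getInfo(info, "SPAN")),
      tsdelStart = if (is.na(tsdel)) NA_integer_ else
        as.integer(sub("-.*", "", tsdel)),
      tsdelEnd = if (is.na(tsdel)) NA_integer_ else
        as.integer(sub(".*-", "", tsdel)),
      genotype = if (gtf[1] == "./.") NA_character_ else gtf[1],
      gq = if (length(gtf) < 2 || gtf[2] == ".") NA_real_ else
        as.numeric(gtf[2]),
      provenance = getInfo(info, "PROV"),
      insSeq = getInfo(info, "INSSEQ"))
    gr
  }
  InsertionCallSet(do.call(c, lapply(f, one)))
}

#' Write candidate sites as BED (0-based half-open)
#'
#' @param callset An \code{\link{InsertionCallSet}}.
#' @param path Output path.
#' @export
writeCallsBed <- function(callset, path) {
  gr <- insertionCalls(callset)
  rows <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                paste0(mcols(gr)$family, ":", mcols(gr)$subfamily),
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}
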