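#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Consensus library of transposable-element sequences
#'
#' Holds one consensus sequence per subfamily together with the
#' subfamily-to-family map and, optionally, an index of 3'-flank windows
#' downstream of full-length source elements used for transduction tracing.
#'
#' @slot seqs A \code{DNAStringSet}, one record per subfamily.
#' @slot family Named character vector mapping subfamily -> family.
#' @slot flankIndex \code{GRanges} of 3'-flank windows of full-length
#'   source elements (mcols: \code{sourceId}).
#' @slot flankSeqs \code{DNAStringSet} of the flank window sequences,
#'   parallel to \code{flankIndex}.
#' @export
setClass("ConsensusLibrary",
  representation(
    seqs = "DNAStringSet",
    family = "character",
    flankIndex = "GRanges",
    flankSeqs = "DNAStringSet"
  )
)

setValidity("ConsensusLibrary", function(object) {
  msg <- NULL
  if (length(object@seqs) == 0L) msg <- c(msg, "library has no records")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "records must have unique subfamily names")
  if (!all(names(object@seqs) %in% names(object@family)))
    msg <- c(msg, "every subfamily must map to a family")
  if (any(Biostrings::width(object@seqs) == 0L))
    msg <- c(msg, "consensus sequences must be nonempty")
  bad <- grepl("[^ACGTN]", as.character(object@seqs))
  if (any(bad)) msg <- c(msg, "sequences must be uppercase A/C/G/T/N")
  if (length(object@flankIndex) != length(object@flankSeqs))
    msg <- c(msg, "flankIndex and flankSeqs must be parallel")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ConsensusLibrary
#'
#' @param seqs Named \code{DNAStringSet} (names are subfamily labels).
#' @param family Named character vector, subfamily -> family label.
#' @param flankIndex,flankSeqs Optional transduction-source flank index.
#' @return A \code{ConsensusLibrary}.
#' @export
ConsensusLibrary <- function(seqs, family,
                             flankIndex = GRanges(),
                             flankSeqs = DNAStringSet()) {
  new("ConsensusLibrary", seqs = seqs, family = family,
      flankIndex = flankIndex, flankSeqs = flankSeqs)
}

#' @describeIn ConsensusLibrary-class Consensus sequences.
#' @param x A \code{ConsensusLibrary}.
#' @export
consensusSeqs <- function(x) x@seqs

#' @describeIn ConsensusLibrary-class Family of each subfamily label.
#' @param subfamily Subfamily label(s).
#' @export
familyOf <- function(x, subfamily) unname(x@family[subfamily])

#' @describeIn ConsensusLibrary-class Transduction-source flank windows.
#' @export
flankIndex <- function(x) x@flankIndex

#' @describeIn ConsensusLibrary-class Flank window sequences.
#' @export
flankSeqs <- function(x) x@flankSeqs

setMethod("show", "ConsensusLibrary", function(object) {
  cat("ConsensusLibrary with", length(object@seqs), "records:",
      paste(sprintf("%s(%s,%dbp)", names(object@seqs),
                    unname(object@family[names(object@seqs)]),
                    Biostrings::width(object@seqs)), collapse = " "), "\n")
  if (length(object@flankIndex))
    cat(" ", length(object@flankIndex), "indexed source flank windows\n")
})

#' Sequencing-library statistics
#'
#' Insert-size moments, read length and mean depth estimated from a
#' short-read alignment stream; these calibrate the mu + 3*sigma cluster
#' distance gate and the depth-scaled calling thresholds.
#'
#' @slot meanInsert,sdInsert Insert-size mean / standard deviation (bp).
#' @slot readLength Read length (bp).
#' @slot meanDepth Mean fold coverage.
#' @export
setClass("LibraryStats",
  representation(meanInsert = "numeric", sdInsert = "numeric",
                 readLength = "numeric", meanDepth = "numeric")
)

setValidity("LibraryStats", function(object) {
  v <- c(object@meanInsert, object@sdInsert, object@readLength, object@meanDepth)
  if (any(!is.finite(v)) || any(v <= 0)) return("all statistics must be positive")
  if (object@sdInsert >= object@meanInsert)
    return("sd_insert must be smaller than mean_insert")
  TRUE
})

#' Construct LibraryStats
#' @param meanInsert,sdInsert,readLength,meanDepth See class slots.
#' @return A \code{LibraryStats}.
#' @export
LibraryStats <- function(meanInsert, sdInsert, readLength, meanDepth) {
  new("LibraryStats", meanInsert = as.numeric(meanInsert),
      sdInsert = as.numeric(sdInsert), readLength = as.numeric(readLength),
      meanDepth = as.numeric(meanDepth))
}

#' @describeIn LibraryStats-class Accessors.
#' @param x A \code{LibraryStats}.
#' @export
meanInsert <- function(x) x@meanInsert
#' @describeIn LibraryStats-class Insert-size standard deviation.
#' @export
sdInsert <- function(x) x@sdInsert
#' @describeIn LibraryStats-class Read length.
#' @export
readLength <- function(x) x@readLength
#' @describeIn LibraryStats-class Mean depth.
#' @export
meanDepth <- function(x) x@meanDepth

setMethod("show", "LibraryStats", function(object) {
  cat(sprintf("LibraryStats: insert %.1f +/- %.1f bp, read length %d bp, depth %.1fX\n",
              object@meanInsert, object@sdInsert,
              as.integer(object@readLength), object@meanDepth))
})

## Metadata columns every InsertionCallSet GRanges carries.
.callCols <- c("family", "subfamily", "leftBp", "rightBp", "orientation",
               "tsdSeq", "tsdLen", "polyALen", "polyASide",
               "tdKind", "tdChrom", "tdStart", "tdEnd",
               "clipLeft", "clipRight", "disc", "spanning",
               "tsdelStart", "tsdelEnd", "genotype", "gq",
               "provenance", "insSeq")

#' Set of nonreference TE insertion calls
#'
#' Wraps a \code{GRanges} (one range per insertion, anchored at the left
#' breakpoint) whose metadata columns carry family/subfamily, breakpoints,
#' TSD/polyA signatures, transduction source, support counts, target-site
#' deletion, genotype and provenance.
#'
#' @slot calls The underlying \code{GRanges}.
#' @export
setClass("InsertionCallSet", representation(calls = "GRanges"))

setValidity("InsertionCallSet", function(object) {
  missing <- setdiff(.callCols, colnames(mcols(object@calls)))
  if (length(missing))
    return(paste("missing call columns:", paste(missing, collapse = ", ")))
  gt <- mcols(object@calls)$genotype
  if (!all(is.na(gt) | gt %in% c("0/0", "0/1", "1/1")))
    return("genotype must be 0/0, 0/1, 1/1 or NA")
  TRUE
})

#' Construct an InsertionCallSet
#'
#' @param calls A \code{GRanges} with the call metadata columns; missing
#'   columns are filled with defaults.
#' @return An \code{InsertionCallSet} sorted by (chrom, position).
#' @export
InsertionCallSet <- function(calls = GRanges()) {
  mc <- mcols(calls)
  defaults <- list(
    family = NA_character_, subfamily = NA_character_,
    leftBp = NA_integer_, rightBp = NA_integer_, orientation = "+",
    tsdSeq = "", tsdLen = 0L, polyALen = 0L, polyASide = "none",
    tdKind = "none", tdChrom = NA_character_, tdStart = NA_integer_,
    tdEnd = NA_integer_, clipLeft = 0L, clipRight = 0L, disc = 0L,
    spanning = 0L, tsdelStart = NA_integer_, tsdelEnd = NA_integer_,
    genotype = NA_character_, gq = NA_real_, provenance = "short",
    insSeq = NA_character_)
  for (nm in .callCols)
    if (!nm %in% colnames(mc)) mc[[nm]] <- rep(defaults[[nm]], length(calls))
  mcols(calls) <- mc[, .callCols, drop = FALSE]
  calls <- calls[order(as.character(seqnames(calls)), start(calls))]
  new("InsertionCallSet", calls = calls)
}

#' @describeIn InsertionCallSet-class Underlying \code{GRanges}.
#' @param x An \code{InsertionCallSet}.
#' @export
insertionCalls <- function(x) x@calls

#' @describeIn InsertionCallSet-class Number of calls.
#' @param object An \code{InsertionCallSet}.
#' @export
setMethod("length", "InsertionCallSet", function(x) length(x@calls))

#' @describeIn InsertionCallSet-class Subset calls.
#' @param i Index.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "InsertionCallSet", function(x, i, j, ..., drop = TRUE) {
  new("InsertionCallSet", calls = x@calls[i])
})

#' Coerce calls to a data.frame
#' @param x An \code{InsertionCallSet}.
#' @param ... Passed on.
#' @export
as.data.frame.InsertionCallSet <- function(x, ...) {
  as.data.frame(x@calls, ...)
}

setMethod("as.data.frame", "InsertionCallSet", function(x, ...) {
  as.data.frame(x@calls, ...)
})

setMethod("show", "InsertionCallSet", function(object) {
  n <- length(object@calls)
  cat("InsertionCallSet with", n, "calls\n")
  if (n) {
    tab <- table(mcols(object@calls)$family, useNA = "ifany")
    cat("  families:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    print(utils::head(as.data.frame(object@calls)[,
      c("seqnames", "start", "family", "subfamily", "genotype", "provenance")], 5))
    if (n > 5) cat("  ...\n")
  }
})

#' Combine call sets
#' @param x,... \code{InsertionCallSet} objects.
#' @export
setMethod("c", "InsertionCallSet", function(x, ...) {
  grs <- lapply(c(list(x), list(...)), insertionCalls)
  InsertionCallSet(suppressWarnings(do.call(c, grs)))
})
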