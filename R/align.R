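## Pairwise alignment contract shared by all modules.
##
## Fixed scoring: match +2, mismatch -4, gap open -4, gap extend -2.
## Both orientations are tried; ties break to the lowest target start and
## then to the + orientation, so results are deterministic.

.alnMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                           baseOnly = FALSE)
}

.alnOne <- function(query, target, type) {
  pa <- Biostrings::pairwiseAlignment(query, target, type = type,
                                      substitutionMatrix = .alnMat(),
                                      gapOpening = 4, gapExtension = 2)
  alnLen <- nchar(pa)      # alignment length, without string extraction
  nm <- Biostrings::nmatch(pa)
  list(score = Biostrings::score(pa),
       qstart = Biostrings::start(Biostrings::pattern(pa)),
       qend = Biostrings::end(Biostrings::pattern(pa)),
       tstart = Biostrings::start(Biostrings::subject(pa)),
       tend = Biostrings::end(Biostrings::subject(pa)),
       identity = if (alnLen > 0) 100 * nm / alnLen else 0,
       alnLen = alnLen)
}

#' Align two sequences under the package's fixed scoring
#'
#' Best local (or glocal, i.e. whole-query) alignment of \code{query}
#' against \code{target}, trying both orientations. Scoring is fixed
#' (match +2, mismatch -4, gap open -4, gap extend -2) with a
#' deterministic tie-break (lower target start, then + orientation).
#'
#' @param query,target DNA sequences (character or \code{DNAString}).
#' @param mode \code{"local"} (Smith-Waterman) or \code{"glocal"}
#'   (whole query against a target window).
#' @return A list with \code{score}, query/target coordinates (1-based,
#'   on the forward target), \code{identity} (percent), \code{orientation}
#'   (\code{"+"}/\code{"-"}), \code{alnLen}, and the query clip lengths
#'   \code{clipLeft}/\code{clipRight}.
#' @examples
#' alignPair("ACGTACGT", "ACGTACGT")$identity
#' @export
alignPair <- function(query, target, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  query <- as.character(query); target <- as.character(target)
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  type <- if (mode == "local") "local" else "global-local"
  fwd <- .alnOne(DNAString(query), DNAString(target), type)
  rev <- .alnOne(reverseComplement(DNAString(query)), DNAString(target), type)
  pick <- if (rev$score > fwd$score) "-"
          else if (fwd$score > rev$score) "+"
          else if (rev$tstart < fwd$tstart) "-" else "+"
  a <- if (pick == "-") rev else fwd
  qlen <- nchar(query)
  qs <- a$qstart; qe <- a$qend
  if (pick == "-") {   # report query coordinates on the original strand
    qs2 <- qlen - qe + 1L; qe <- qlen - a$qstart + 1L; qs <- qs2
  }
  list(score = a$score, qstart = qs, qend = qe,
       tstart = a$tstart, tend = a$tend,
       identity = a$identity, orientation = pick, alnLen = a$alnLen,
       clipLeft = qs - 1L, clipRight = qlen - qe)
}

## Batch local alignment of many queries against one target, both
## orientations in two vectorised calls. Returns a data.frame with one row
## per query: score, tstart, tend, identity, orientation, qcov (percent of
## query aligned).
alignBatch <- function(queries, target) {
  if (!length(queries)) {
    return(data.frame(score = numeric(0), tstart = integer(0),
                      tend = integer(0), identity = numeric(0),
                      orientation = character(0), qcov = numeric(0)))
  }
  qs <- DNAStringSet(queries)
  subj <- DNAString(as.character(target))
  mat <- .alnMat()
  res <- lapply(list(`+` = qs, `-` = reverseComplement(qs)), function(q) {
    pa <- Biostrings::pairwiseAlignment(q, subj, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 4, gapExtension = 2)
    alnLen <- nchar(pa)    # alignment length, without string extraction
    data.frame(score = Biostrings::score(pa),
               tstart = Biostrings::start(Biostrings::subject(pa)),
               tend = Biostrings::end(Biostrings::subject(pa)),
               qal = Biostrings::width(Biostrings::pattern(pa)),
               identity = ifelse(alnLen > 0,
                                 100 * Biostrings::nmatch(pa) / alnLen, 0))
  })
  useRev <- res[["-"]]$score > res[["+"]]$score
  out <- res[["+"]]
  out[useRev, ] <- res[["-"]][useRev, ]
  out$orientation <- ifelse(useRev, "-", "+")
  out$qcov <- 100 * out$qal / Biostrings::width(qs)
  out$qal <- NULL
  out
}

#' Classify a sequence against the consensus library
#'
#' Best-scoring local alignment of \code{seq} against every library record
#' (both orientations); the label is reported only when identity and query
#' coverage pass the thresholds. A surrogate for running RepeatMasker on
#' assembled sequences.
#'
#' @param seq DNA sequence, at least 30 bp.
#' @param library A \code{\link{ConsensusLibrary}}.
#' @param minIdentityPct,minCoveragePct Acceptance thresholds (defaults
#'   80 and 50).
#' @return A list with \code{family}, \code{subfamily}, \code{identityPct},
#'   \code{queryCoveragePct}, \code{orientation}, or \code{NULL} when no
#'   record passes.
#' @export
classifySequence <- function(seq, library, minIdentityPct = 80,
                             minCoveragePct = 50) {
  seq <- as.character(seq)
  if (nchar(seq) < 30)
    stop("sequence shorter than 30 bp cannot be classified")
  recs <- consensusSeqs(library)
  cand <- seq_along(recs)
  if (nchar(seq) > 1500L && length(recs) > 2L) {
    ## prescreen long queries with three 300 bp windows, then align in
    ## full only against the top two records
    n <- nchar(seq)
    wins <- c(substr(seq, 1L, 300L),
              substr(seq, n %/% 2L - 149L, n %/% 2L + 150L),
              substr(seq, n - 299L, n))
    pre <- vapply(cand, function(i) {
      sum(vapply(wins, function(w) alignPair(w, recs[[i]])$score, 0))
    }, 0)
    cand <- cand[order(-pre)][1:2]
    cand <- sort(cand)
  }
  best <- NULL
  for (i in cand) {
    a <- alignPair(seq, recs[[i]], mode = "local")
    if (is.null(best) || a$score > best$score) {
      best <- a
      best$subfamily <- names(recs)[i]
    }
  }
  cov <- 100 * (best$qend - best$qstart + 1) / nchar(seq)
  if (best$identity >= minIdentityPct && cov >= minCoveragePct) {
    list(family = familyOf(library, best$subfamily),
         subfamily = best$subfamily,
         identityPct = best$identity,
         queryCoveragePct = cov,
         orientation = best$orientation,
         tstart = best$tstart, tend = best$tend,
         qstart = best$qstart, qend = best$qend)
  } else NULL
}
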