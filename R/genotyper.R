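## Machine-learning genotyping of TE insertions.
##
## A fixed 14-feature schema describes the read support at a call site;
## training labels come from trio evidence rules; the classifier is a
## seeded random forest over {0/0, 0/1, 1/1}.

#' The 14-feature genotype schema
#'
#' Order is fixed and versioned into serialized models.
#' @return Character vector of the 14 feature names.
#' @export
genotypeFeatureNames <- function() {
  c("clipLeft", "clipRight", "disc", "spanning", "discRatio",
    "fullyMappedLeft", "fullyMappedRight", "polyASupport", "tsdLen",
    "meanMapq", "clipConcordance", "localDepth",
    "clipLeftNorm", "clipRightNorm")
}

#' Extract genotype features at a call site
#'
#' Counts are taken from the alignment table around the call breakpoints;
#' the clip counts are also reported normalized by the mean sequencing
#' depth. A site with no coverage yields an all-zero (0/0-like) vector.
#'
#' @param call One-call \code{\link{InsertionCallSet}} or a list with
#'   \code{chrom}, \code{leftBp}, \code{rightBp}.
#' @param tbl Alignment table.
#' @param stats \code{\link{LibraryStats}} (depth normalizer).
#' @param window Breakpoint tolerance for clip matching (default 5 bp).
#' @return Named numeric vector of length 14.
#' @export
extractFeatures <- function(call, tbl, stats, window = 5L) {
  if (is(call, "InsertionCallSet")) {
    gr <- insertionCalls(call)[1]
    chrom <- as.character(seqnames(gr))
    leftBp <- mcols(gr)$leftBp; rightBp <- mcols(gr)$rightBp
  } else {
    chrom <- call$chrom; leftBp <- call$leftBp; rightBp <- call$rightBp
  }
  if (is.na(rightBp)) rightBp <- leftBp
  use <- tbl$isMapped & !tbl$isSupp & !tbl$isDup & tbl$chrom == chrom
  near <- use & tbl$pos <= rightBp + 1000L & tbl$endpos >= leftBp - 1000L
  sub <- tbl[near, , drop = FALSE]
  ## left-clipped reads anchor at the left breakpoint (the smaller
  ## anchor, inside the TSD), right-clipped reads at the right one
  clipL <- sum(sub$clipL >= 10L & abs((sub$pos - 1L) - leftBp) <= window)
  clipR <- sum(sub$clipR >= 10L & abs(sub$endpos - rightBp) <= window)
  disc <- sum(!sub$isProper & sub$pos <= rightBp + 600L &
                sub$endpos >= leftBp - 600L)
  spanning <- sum(sub$isProper & sub$clipL == 0L & sub$clipR == 0L &
                    sub$pos < leftBp - window & sub$endpos > rightBp + window)
  ratio <- if (disc + spanning > 0) disc / (disc + spanning) else 0
  fmL <- sum(sub$clipL == 0L & sub$clipR == 0L &
               sub$pos < leftBp & sub$endpos > leftBp)
  fmR <- sum(sub$clipL == 0L & sub$clipR == 0L &
               sub$pos < rightBp & sub$endpos > rightBp)
  clipRows <- which((sub$clipR >= 10L & abs(sub$endpos - rightBp) <= window) |
                      (sub$clipL >= 10L & abs((sub$pos - 1L) - leftBp) <= window))
  polyA <- 0L
  for (i in clipRows) {
    s <- if (sub$clipR[i] >= 10L)
      clipSeq(sub$seq[i], sub$clipL[i], sub$clipR[i], "right")
    else clipSeq(sub$seq[i], sub$clipL[i], sub$clipR[i], "left")
    if (!is.na(s) && polyASignal(s)$len >= 5L) polyA <- polyA + 1L
  }
  tsdLen <- if (!is.na(leftBp) && !is.na(rightBp)) rightBp - leftBp else 0L
  suppRows <- unique(c(clipRows, which(!sub$isProper)))
  meanMapq <- if (length(suppRows)) mean(sub$mapq[suppRows]) else 0
  anchors <- c(sub$endpos[sub$clipR >= 10L &
                            abs(sub$endpos - rightBp) <= window],
               (sub$pos - 1L)[sub$clipL >= 10L &
                                abs((sub$pos - 1L) - leftBp) <= window])
  conc <- if (length(anchors))
    max(table(anchors)) / length(anchors) else 0
  dwin <- 200L
  cov <- sum(sub$pos <= rightBp + dwin & sub$endpos >= leftBp - dwin) *
    readLength(stats) / (rightBp - leftBp + 2 * dwin + readLength(stats))
  d <- meanDepth(stats)
  out <- c(clipL, clipR, disc, spanning, ratio, fmL, fmR, polyA,
           max(tsdLen, 0L), meanMapq, conc, cov, clipL / d, clipR / d)
  names(out) <- genotypeFeatureNames()
  out
}

#' Trio evidence rules for training labels
#'
#' Heterozygous (1) when the call was made in exactly one parent and the
#' other has no supporting clips; reference homozygous (0) when neither
#' parent has supporting clips; alternate homozygous (2) when both parents
#' carry the call, the discordant/(discordant+concordant) ratio exceeds
#' \code{ratioThreshold} (strictly), and no fully mapped reads cross the
#' breakpoints. Sites matching none of the rules are excluded (NA).
#'
#' @param calledIn Character subset of c("father", "mother") where the
#'   call was made.
#' @param support Named list per parent with \code{clip}, \code{disc},
#'   \code{concordant}, \code{fullyMapped} counts.
#' @param ratioThreshold Default 0.85.
#' @return 0, 1, 2 or NA.
#' @export
labelTrainingSite <- function(calledIn, support, ratioThreshold = 0.85) {
  clips <- vapply(support, `[[`, 0, "clip")
  if (length(calledIn) == 1L) {
    other <- setdiff(names(support), calledIn)
    if (clips[[other]] == 0) return(1L)
    return(NA_integer_)
  }
  if (length(calledIn) == 0L) {
    if (all(clips == 0)) return(0L)
    return(NA_integer_)
  }
  ## called in both parents
  disc <- sum(vapply(support, `[[`, 0, "disc"))
  conc <- sum(vapply(support, `[[`, 0, "concordant"))
  fm <- sum(vapply(support, `[[`, 0, "fullyMapped"))
  ratio <- if (disc + conc > 0) disc / (disc + conc) else 0
  if (ratio > ratioThreshold && fm == 0) return(2L)
  NA_integer_
}

#' Train the random-forest genotyper
#'
#' Seeded stratified 70/30 split, 200-tree forest, held-out accuracy.
#'
#' @param features Numeric matrix (rows = sites, 14 columns) or data.frame.
#' @param labels Integer labels in {0, 1, 2}.
#' @param trainFraction Default 0.7.
#' @param ntree Default 200.
#' @param seed RNG seed.
#' @return list(model, schema, heldOutAccuracy, trainIdx).
#' @export
trainGenotyper <- function(features, labels, trainFraction = 0.7,
                           ntree = 200L, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  present <- sort(unique(labels))
  missing <- setdiff(0:2, present)
  if (length(missing))
    stop("training labels lack class(es): ",
         paste(missing, collapse = ", "))
  colnames(features) <- genotypeFeatureNames()
  y <- factor(labels, levels = 0:2)
  trainIdx <- withSeed(seed, {
    unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1L, round(trainFraction * length(idx))))
    }))
  })
  fit <- withSeed(seed + 1L, {
    randomForest::randomForest(x = features[trainIdx, , drop = FALSE],
                               y = y[trainIdx], ntree = ntree)
  })
  test <- setdiff(seq_along(y), trainIdx)
  acc <- if (length(test)) {
    pred <- stats::predict(fit, features[test, , drop = FALSE])
    mean(pred == y[test])
  } else NA_real_
  list(model = fit, schema = genotypeFeatureNames(), schemaVersion = 1L,
       heldOutAccuracy = acc, trainIdx = trainIdx)
}

#' Predict a genotype from a 14-feature vector
#'
#' @param model From \code{\link{trainGenotyper}}.
#' @param features Numeric vector of length 14 (or matrix of rows).
#' @return Integer label(s) in {0, 1, 2}.
#' @export
predictGenotype <- function(model, features) {
  m <- if (is.null(dim(features))) matrix(features, nrow = 1L)
       else as.matrix(features)
  if (ncol(m) != length(model$schema))
    stop(sprintf("feature schema mismatch: expected %d features, got %d",
                 length(model$schema), ncol(m)))
  colnames(m) <- model$schema
  as.integer(as.character(stats::predict(model$model, m)))
}

#' Genotype label as a VCF GT string
#' @param label Integer 0/1/2.
#' @return "0/0", "0/1" or "1/1".
#' @export
genotypeString <- function(label) c("0/0", "0/1", "1/1")[label + 1L]

#' Mendelian consistency of a trio genotype
#'
#' Consistent iff the child genotype is reachable by transmitting one
#' allele from each parent under the biallelic model: a parent with
#' genotype 0 transmits allele 0, genotype 2 transmits allele 1, and
#' genotype 1 transmits either.
#'
#' @param father,mother,child Genotypes in {0, 1, 2}.
#' @return TRUE (consistent) or FALSE.
#' @export
checkMendelianConsistency <- function(father, mother, child) {
  alleles <- function(g) switch(as.character(g), "0" = 0L, "1" = c(0L, 1L),
                                "2" = 1L, stop("invalid genotype"))
  possible <- unique(as.vector(outer(alleles(father), alleles(mother), "+")))
  child %in% possible
}
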