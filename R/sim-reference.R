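## Deterministic synthetic-data generator: miniature reference genomes
## with planted repeats, satellites, solo LTRs and genes, plus a
## miniature TE consensus set. All randomness is locally seeded so
## identical configurations reproduce byte-identical outputs.

#' Miniature TE consensus library
#'
#' A deterministic miniature consensus set (L1 6 kb with a seeded
#' subfamily variant, Alu 300 bp x2, SVA 1.3 kb, LTR 1 kb, HERV internal
#' 7.2 kb, and Alpha/Beta/HSATII satellite arrays). The set is generated
#' from a fixed internal seed, so it is identical across sessions.
#'
#' @return A \code{\link{ConsensusLibrary}} (without a flank index; the
#'   index is attached by \code{\link{simulateReference}}).
#' @export
miniConsensusLibrary <- function() {
  withSeed(990721L, {
    l1 <- randomDna(6000L)
    alu <- randomDna(300L)
    sva <- randomDna(1300L)
    ltr <- randomDna(1000L)
    herv <- randomDna(7200L)
    tandem <- function(monomerLen, copies, divPerCopy) {
      mono <- randomDna(monomerLen)
      paste(vapply(seq_len(copies), function(i)
        mutateSeqs(mono, divPerCopy), ""), collapse = "")
    }
    seqs <- DNAStringSet(c(
      L1HS = l1,
      L1PA2 = mutateSeqs(l1, 0.03),
      AluYa5 = alu,
      AluYb8 = mutateSeqs(alu, 0.02),
      SVA_E = sva,
      LTR5 = ltr,
      HERVK_int = herv,
      ALR_Alpha = tandem(171L, 12L, 0.10),
      BSR_Beta = tandem(68L, 30L, 0.10),
      HSATII = tandem(26L, 80L, 0.10)))
    fam <- c(L1HS = "L1", L1PA2 = "L1", AluYa5 = "Alu", AluYb8 = "Alu",
             SVA_E = "SVA", LTR5 = "LTR", HERVK_int = "HERV",
             ALR_Alpha = "Alpha", BSR_Beta = "Beta", HSATII = "HSATII")
    ConsensusLibrary(seqs, fam)
  })
}

#' Simulation configuration
#'
#' Collects all generator knobs with the package's default study
#' conditions. Event counts are given in \code{events} as a data.frame
#' with columns \code{type}, \code{count} and optional per-type
#' parameters.
#'
#' @param seed Master seed (all outputs are deterministic given it).
#' @param genomeLength Reference length in bp.
#' @param chrom Chromosome name.
#' @param nRefAlu,nRefL1 Background reference repeat copies.
#' @param nFullL1 Full-length reference L1 copies (transduction sources /
#'   ghost donors), each with an indexed unique 2 kb downstream flank.
#' @param satelliteBlocks data.frame(class, length) of satellite blocks.
#' @param nSoloLtr Solo-LTR loci.
#' @param nGenes Genes (3-4 exons each) for pseudogene calling.
#' @param events data.frame(type, count, ...).
#' @param shortRead list(depth, readLen, meanInsert, sdInsert, errorRate).
#' @param longRead list(depth, meanLen, sdLen, minLen, errorRate,
#'   ghostReads).
#' @return A config list.
#' @export
simConfig <- function(seed = 1L,
                      genomeLength = 2000000L,
                      chrom = "chr1",
                      nRefAlu = 8L, nRefL1 = 4L, nFullL1 = 3L,
                      satelliteBlocks = data.frame(
                        class = c("Alpha", "Beta", "HSATII"),
                        length = c(8000L, 4000L, 4000L)),
                      nSoloLtr = 2L, nGenes = 2L,
                      events = data.frame(type = "alu", count = 5L),
                      shortRead = list(depth = 30, readLen = 150L,
                                       meanInsert = 500, sdInsert = 50,
                                       errorRate = 0.002),
                      longRead = list(depth = 20, meanLen = 12000L,
                                      sdLen = 2000L, minLen = 3000L,
                                      errorRate = 0.01, ghostReads = 6L)) {
  stopifnot(genomeLength > 50000L, shortRead$sdInsert < shortRead$meanInsert)
  list(seed = as.integer(seed), genomeLength = as.integer(genomeLength),
       chrom = chrom, nRefAlu = nRefAlu, nRefL1 = nRefL1,
       nFullL1 = nFullL1, satelliteBlocks = satelliteBlocks,
       nSoloLtr = nSoloLtr, nGenes = nGenes, events = events,
       shortRead = shortRead, longRead = longRead)
}

## Replace genome[at..at+len-1] with seq (character surgery).
.put <- function(genome, at, seq) {
  paste0(substr(genome, 1L, at - 1L), seq,
         substr(genome, at + nchar(seq), nchar(genome)))
}

#' Build a synthetic reference with planted repeat annotation
#'
#' Deterministic for a given config: plants diverged Alu/L1 background
#' copies, full-length L1 sources with unique indexed 3' flanks,
#' satellite blocks, solo LTRs and a small gene set, and records them in
#' a RepeatMasker-style annotation plus a transcript table.
#'
#' @param config From \code{\link{simConfig}}.
#' @return A list: \code{chrom}, \code{seq} (character genome),
#'   \code{refLens}, \code{rmsk} (\code{GRanges}), \code{transcripts},
#'   \code{library} (\code{\link{ConsensusLibrary}} with flank index),
#'   \code{fullL1s}, \code{soloLtrs}, \code{satBlocks} (\code{GRanges}),
#'   \code{config}.
#' @export
simulateReference <- function(config) {
  lib <- miniConsensusLibrary()
  recs <- consensusSeqs(lib)
  withSeed(config$seed, {
    G <- config$genomeLength
    genome <- randomDna(G)
    occupied <- matrix(numeric(0), ncol = 2)
    place <- function(len, pad = 2500L) {
      for (try in 1:2000) {
        at <- sample.int(G - len - 3L * pad, 1L) + pad
        if (!nrow(occupied) ||
            all(at > occupied[, 2] + pad | at + len - 1L < occupied[, 1] - pad)) {
          occupied <<- rbind(occupied, c(at, at + len - 1L))
          return(at)
        }
      }
      stop("reference too small to place all planted elements")
    }
    ann <- list()
    addAnn <- function(at, len, family, subfamily, div, strand = "+") {
      gr <- GRanges(config$chrom, IRanges(at, at + len - 1L),
                    strand = strand)
      mcols(gr) <- DataFrame(family = family, subfamily = subfamily,
                             divergencePct = div, isFullLength = NA)
      ann[[length(ann) + 1L]] <<- gr
    }
    ## background Alu copies at mixed divergence
    for (i in seq_len(config$nRefAlu)) {
      subf <- sample(c("AluYa5", "AluYb8"), 1L)
      div <- sample(c(1, 2, 3, 8, 12, 15, 20), 1L)
      s <- mutateSeqs(as.character(recs[[subf]]), div / 100)
      at <- place(nchar(s))
      genome <- .put(genome, at, s)
      addAnn(at, nchar(s), "Alu", subf, div)
    }
    ## background truncated L1 copies
    for (i in seq_len(config$nRefL1)) {
      keep <- sample(1500:4000, 1L)
      div <- sample(c(2, 5, 10, 15, 20), 1L)
      full <- as.character(recs[["L1HS"]])
      s <- mutateSeqs(substr(full, nchar(full) - keep + 1L, nchar(full)),
                      div / 100)
      at <- place(nchar(s))
      genome <- .put(genome, at, s)
      addAnn(at, nchar(s), "L1", "L1HS", div)
    }
    ## full-length L1 sources (low divergence) with unique 2 kb flanks
    fullIdx <- integer(0)
    for (i in seq_len(config$nFullL1)) {
      div <- stats::runif(1, 0.5, 2)
      s <- mutateSeqs(as.character(recs[["L1HS"]]), div / 100)
      at <- place(nchar(s) + 2000L)
      genome <- .put(genome, at, s)
      addAnn(at, nchar(s), "L1", "L1HS", round(div, 1))
      fullIdx <- c(fullIdx, length(ann))
    }
    ## satellite blocks: fresh tandem arrays built from the library class
    satIdx <- integer(0)
    for (i in seq_len(nrow(config$satelliteBlocks))) {
      cls <- config$satelliteBlocks$class[i]
      len <- config$satelliteBlocks$length[i]
      rec <- switch(cls, Alpha = "ALR_Alpha", Beta = "BSR_Beta",
                    HSATII = "HSATII")
      unitSeq <- as.character(recs[[rec]])
      reps <- ceiling(len / nchar(unitSeq))
      s <- substr(paste(vapply(seq_len(reps), function(k)
        mutateSeqs(unitSeq, 0.08), ""), collapse = ""), 1L, len)
      at <- place(len)
      genome <- .put(genome, at, s)
      addAnn(at, len, cls, rec, 8)
      satIdx <- c(satIdx, length(ann))
    }
    ## solo LTRs
    ltrIdx <- integer(0)
    for (i in seq_len(config$nSoloLtr)) {
      s <- mutateSeqs(as.character(recs[["LTR5"]]), 0.01)
      at <- place(nchar(s))
      genome <- .put(genome, at, s)
      addAnn(at, nchar(s), "LTR", "LTR5", 1)
      ltrIdx <- c(ltrIdx, length(ann))
    }
    ## genes: 3-4 exons of 150-200 bp separated by 300-800 bp introns
    tx <- list()
    for (g in seq_len(config$nGenes)) {
      nex <- sample(3:4, 1L)
      sizes <- sample(150:200, nex, replace = TRUE)
      gaps <- sample(300:800, nex - 1L, replace = TRUE)
      span <- sum(sizes) + sum(gaps)
      at <- place(span)
      es <- at + cumsum(c(0L, sizes[-nex] + gaps))
      ee <- es + sizes - 1L
      tx[[g]] <- data.frame(chrom = config$chrom, gene = paste0("GENE", g),
                            txStart = at, txEnd = at + span - 1L)
      tx[[g]]$exonStarts <- list(es)
      tx[[g]]$exonEnds <- list(ee)
    }
    transcripts <- do.call(rbind, tx)
    rmsk <- do.call(c, ann)
    rmsk <- annotateFullLength(rmsk, lib)
    fullL1s <- rmsk[fullIdx]
    ## transduction-source flank index: 2 kb downstream of each full L1
    fi <- GRanges(config$chrom,
                  IRanges(end(fullL1s) + 1L, end(fullL1s) + 2000L))
    mcols(fi) <- DataFrame(sourceId = paste0("srcL1_", seq_along(fi)),
                           sourceFamily = "L1")
    fseqs <- DNAStringSet(substring(genome, start(fi), end(fi)))
    names(fseqs) <- mcols(fi)$sourceId
    lib2 <- ConsensusLibrary(consensusSeqs(lib), lib@family,
                             flankIndex = fi, flankSeqs = fseqs)
    refLens <- structure(nchar(genome), names = config$chrom)
    o <- order(start(rmsk))
    list(chrom = config$chrom, seq = genome, refLens = refLens,
         rmsk = rmsk[o], transcripts = transcripts, library = lib2,
         fullL1s = fullL1s, soloLtrs = rmsk[o][mcols(rmsk[o])$family == "LTR"],
         satBlocks = rmsk[o][mcols(rmsk[o])$family %in%
                               c("Alpha", "Beta", "HSATII")],
         config = config)
  })
}

#' Write simulator reference outputs to files
#'
#' Emits reference.fa, consensus.fa, rmsk.out and exons.bed.
#'
#' @param ref From \code{\link{simulateReference}}.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
writeSimReference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- DNAStringSet(ref$seq)
  names(g) <- ref$chrom
  Biostrings::writeXStringSet(g, file.path(dir, "reference.fa"))
  Biostrings::writeXStringSet(consensusSeqs(ref$library),
                              file.path(dir, "consensus.fa"))
  writeRepeatmaskerOut(ref$rmsk, file.path(dir, "rmsk.out"))
  writeExonsBed(ref$transcripts, file.path(dir, "exons.bed"))
  invisible(dir)
}
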