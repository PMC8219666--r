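## Read simulation with analytically computed alignments.
##
## Fragments/reads are drawn from the haplotype sequences; alignments
## against the original reference are computed from the event coordinates
## (no external aligner), so reads crossing an insertion junction acquire
## exact soft clips, mates falling inside insertions become unmapped
## discordant evidence, and long reads spanning an insertion carry a
## CIGAR I operation of the true inserted length. Per-base substitution
## errors are injected after the alignment computation, so CIGARs stay
## truthful. Satellite blocks are excluded from ordinary sampling
## (unmappable in practice); ghost-L1 reads are emitted separately as
## donor-mapped both-side-clipped records.

## hap intervals to exclude from ordinary sampling: satellite-derived
## reference pieces and ghost insertion pieces.
.excludedHapIntervals <- function(pieces, satBlocks, truth) {
  ex <- matrix(numeric(0), ncol = 2)
  if (length(satBlocks)) {
    refPieces <- pieces[pieces$type == "ref", , drop = FALSE]
    for (i in seq_len(nrow(refPieces))) {
      p <- refPieces[i, ]
      for (j in seq_along(satBlocks)) {
        a <- max(p$refStart, start(satBlocks)[j])
        b <- min(p$refEnd, end(satBlocks)[j])
        if (a <= b) {
          ex <- rbind(ex, c(p$hapStart + (a - p$refStart),
                            p$hapStart + (b - p$refStart)))
        }
      }
    }
  }
  ghostIds <- truth$id[truth$type == "ghost_l1"]
  if (length(ghostIds)) {
    gp <- pieces[pieces$type == "ins" & pieces$eventId %in% ghostIds, ,
                 drop = FALSE]
    if (nrow(gp)) ex <- rbind(ex, cbind(gp$hapStart, gp$hapEnd))
  }
  ex
}

.overlapsAny <- function(s, e, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(s)))
  out <- rep(FALSE, length(s))
  for (i in seq_len(nrow(intervals)))
    out <- out | (s <= intervals[i, 2] & e >= intervals[i, 1])
  out
}

#' Simulate aligned paired-end short reads
#'
#' @param ref From \code{\link{simulateReference}}.
#' @param planted From \code{\link{plantInsertions}}.
#' @param seed Seed (default config seed + 2).
#' @param depth Total depth (default config).
#' @param keepAllSeq Store the sequence of every read (default FALSE:
#'   sequences are materialized only for clipped and unmapped reads,
#'   where sequence-level evidence is consumed).
#' @return A coordinate-sorted alignment table.
#' @export
simulateShortReads <- function(ref, planted, seed = ref$config$seed + 2L,
                               depth = ref$config$shortRead$depth,
                               keepAllSeq = FALSE) {
  sr <- ref$config$shortRead
  rl <- sr$readLen
  haps <- list(planted$hap1, planted$hap2)
  withSeed(seed, {
    tabs <- list()
    for (h in 1:2) {
      hap <- haps[[h]]
      pieces <- hap$pieces
      hapLen <- nchar(hap$seq)
      nfrag <- round((depth / 2) * hapLen / (2 * rl))
      fl <- pmin(pmax(round(stats::rnorm(nfrag, sr$meanInsert, sr$sdInsert)),
                      2L * rl + 20L), round(sr$meanInsert + 4 * sr$sdInsert))
      fs <- 1L + floor(stats::runif(nfrag) * (hapLen - fl))
      ex <- .excludedHapIntervals(pieces, ref$satBlocks, planted$truth)
      keep <- !.overlapsAny(fs, fs + fl - 1L, ex)
      fs <- fs[keep]; fl <- fl[keep]
      nfrag <- length(fs)
      mapOne <- function(s) {
        ## vectorized over start positions; returns list of vectors
        i <- findInterval(s, pieces$hapStart)
        e <- s + rl - 1L
        isRef <- pieces$type[i] == "ref"
        within <- e <= pieces$hapEnd[i]
        pos <- integer(length(s)); cigar <- character(length(s))
        mapped <- logical(length(s)); need <- logical(length(s))
        ## ref start, fully within
        a <- isRef & within
        pos[a] <- pieces$refStart[i[a]] + (s[a] - pieces$hapStart[i[a]])
        cigar[a] <- paste0(rl, "M"); mapped[a] <- TRUE
        ## ref start, right-clipped at the piece end
        b <- isRef & !within
        m <- pieces$hapEnd[i[b]] - s[b] + 1L
        pos[b] <- pieces$refStart[i[b]] + (s[b] - pieces$hapStart[i[b]])
        cigar[b] <- paste0(m, "M", rl - m, "S")
        mapped[b] <- TRUE; need[b] <- TRUE
        ## insertion start, contained: unmapped (carries insertion seq)
        cc <- !isRef & within
        need[cc] <- TRUE
        ## insertion start, exits into the next (reference) piece
        d <- which(!isRef & !within)
        if (length(d)) {
          j <- i[d] + 1L
          valid <- j <= nrow(pieces) & pieces$type[pmin(j, nrow(pieces))] == "ref"
          dd <- d[valid]; j <- j[valid]
          cl <- pieces$hapEnd[i[dd]] - s[dd] + 1L
          pos[dd] <- pieces$refStart[j]
          cigar[dd] <- paste0(cl, "S", rl - cl, "M")
          mapped[dd] <- TRUE; need[dd] <- TRUE
          need[setdiff(d, dd)] <- TRUE
        }
        list(pos = pos, cigar = cigar, mapped = mapped, need = need)
      }
      r1 <- mapOne(fs)
      r2 <- mapOne(fs + fl - rl)
      getSeq <- function(starts, need) {
        out <- rep(NA_character_, length(starts))
        idx <- if (keepAllSeq) seq_along(starts) else which(need)
        if (length(idx)) {
          sq <- substring(hap$seq, starts[idx], starts[idx] + rl - 1L)
          out[idx] <- mutateSeqs(sq, sr$errorRate)
        }
        out
      }
      seq1 <- getSeq(fs, r1$need)
      ## SAM stores sequences in reference orientation, so the reverse
      ## mate's stored sequence is the forward-haplotype substring
      seq2 <- getSeq(fs + fl - rl, r2$need)
      rw <- function(cigar, mapped) {
        out <- integer(length(cigar))
        cg <- cigar[mapped]
        out[mapped] <- as.integer(sub("M.*$", "", sub("^[0-9]+S", "", cg)))
        out
      }
      rw1 <- rw(r1$cigar, r1$mapped); rw2 <- rw(r2$cigar, r2$mapped)
      bothMapped <- r1$mapped & r2$mapped
      end2 <- r2$pos + rw2 - 1L
      tlen <- ifelse(bothMapped, end2 - r1$pos + 1L, 0L)
      proper <- bothMapped & tlen >= rl &
        tlen <= sr$meanInsert + 4 * sr$sdInsert
      mkFlag <- function(first, mapped, mateMapped, reverse, mateRev) {
        1L + ifelse(proper, 2L, 0L) + ifelse(mapped, 0L, 4L) +
          ifelse(mateMapped, 0L, 8L) + ifelse(reverse, 16L, 0L) +
          ifelse(mateRev, 32L, 0L) + if (first) 64L else 128L
      }
      qn <- sprintf("h%d_%07d", h, seq_len(nfrag))
      pos1 <- ifelse(r1$mapped, r1$pos, ifelse(r2$mapped, r2$pos, 0L))
      pos2 <- ifelse(r2$mapped, r2$pos, ifelse(r1$mapped, r1$pos, 0L))
      tabs[[length(tabs) + 1L]] <- data.frame(
        qname = c(qn, qn),
        flag = c(mkFlag(TRUE, r1$mapped, r2$mapped, FALSE, TRUE),
                 mkFlag(FALSE, r2$mapped, r1$mapped, TRUE, FALSE)),
        chrom = ref$chrom,
        pos = c(pos1, pos2),
        mapq = c(ifelse(r1$mapped, 60L, 0L), ifelse(r2$mapped, 60L, 0L)),
        cigar = c(ifelse(r1$mapped, r1$cigar, NA),
                  ifelse(r2$mapped, r2$cigar, NA)),
        mchrom = ref$chrom,
        mpos = c(pos2, pos1),
        tlen = c(tlen, -tlen),
        seq = c(seq1, seq2))
    }
    tbl <- do.call(rbind, tabs)
    tbl <- tbl[order(tbl$pos), , drop = FALSE]
    rownames(tbl) <- NULL
    alignmentTable(tbl)
  })
}

## Walk the haplotype pieces for one long read; returns a list of SAM-like
## records (possibly primary + supplementary on reference jumps).
.walkLongRead <- function(pieces, s, e, maxDeletionOp = 1500L) {
  i0 <- findInterval(s, pieces$hapStart)
  i1 <- findInterval(e, pieces$hapStart)
  recs <- list()
  cur <- NULL   # list(pos, ops, lens, qconsumed_at_start)
  qdone <- 0L   # query bases consumed in *previous* (closed) records
  qcur <- 0L    # query bases consumed in the current record
  push <- function(op, len) {
    n <- length(cur$ops)
    if (n && cur$ops[n] == op) cur$lens[n] <<- cur$lens[n] + len
    else { cur$ops <<- c(cur$ops, op); cur$lens <<- c(cur$lens, len) }
  }
  closeRec <- function(tailS) {
    if (is.null(cur)) return()
    if (tailS > 0L) { push("S", tailS) }
    recs[[length(recs) + 1L]] <<- cur
    cur <<- NULL
  }
  totalLen <- e - s + 1L
  lastRef <- NA_integer_
  for (p in i0:i1) {
    a <- max(s, pieces$hapStart[p]); b <- min(e, pieces$hapEnd[p])
    L <- b - a + 1L
    if (pieces$type[p] == "ins") {
      if (is.null(cur)) {
        ## read starts inside the insertion: pending leading soft clip,
        ## realized when the next reference piece opens a record
        qcur <- qcur + L
      } else if (p == i1) {
        ## read ends inside the insertion: trailing soft clip
        push("S", L); qcur <- qcur + L
      } else {
        push("I", L); qcur <- qcur + L
      }
    } else {
      refA <- pieces$refStart[p] + (a - pieces$hapStart[p])
      if (is.null(cur)) {
        cur <- list(pos = refA, ops = character(0), lens = integer(0))
        if (qcur > 0L) { cur$ops <- "S"; cur$lens <- qcur }
      } else {
        gap <- refA - lastRef - 1L
        if (gap > 0L && gap <= maxDeletionOp) {
          push("D", gap)
        } else if (gap != 0L) {
          ## large or backward reference jump: split the alignment
          remain <- totalLen - qcur
          consumed <- qcur
          closeRec(remain)
          cur <- list(pos = refA, ops = "S", lens = consumed)
        }
      }
      push("M", L); qcur <- qcur + L
      lastRef <- refA + L - 1L
    }
  }
  closeRec(0L)
  recs
}

#' Simulate aligned long reads
#'
#' Reads spanning an insertion carry a CIGAR insertion operation of the
#' exact inserted length (pre-error); reads ending inside an insertion
#' carry terminal soft clips; reference jumps (SV junctions) split the
#' alignment into a primary plus a supplementary record, each clipped at
#' the junction. Ghost-L1 events emit donor-mapped reads clipped on both
#' sides with satellite flank sequence. Deterministic per seed.
#'
#' @param ref,planted,seed,depth As for \code{\link{simulateShortReads}}.
#' @return A coordinate-sorted alignment table.
#' @export
simulateLongReads <- function(ref, planted, seed = ref$config$seed + 3L,
                              depth = ref$config$longRead$depth) {
  lr <- ref$config$longRead
  haps <- list(planted$hap1, planted$hap2)
  withSeed(seed, {
    rows <- list()
    for (h in 1:2) {
      hap <- haps[[h]]
      pieces <- hap$pieces
      hapLen <- nchar(hap$seq)
      nread <- round((depth / 2) * hapLen / lr$meanLen)
      lens <- pmin(pmax(round(stats::rnorm(nread, lr$meanLen, lr$sdLen)),
                        lr$minLen), 2L * lr$meanLen)
      starts <- 1L + floor(stats::runif(nread) * (hapLen - lens))
      ex <- .excludedHapIntervals(pieces, ref$satBlocks, planted$truth)
      keep <- !.overlapsAny(starts, starts + lens - 1L, ex)
      starts <- starts[keep]; lens <- lens[keep]
      for (k in seq_along(starts)) {
        s <- starts[k]; e <- s + lens[k] - 1L
        seq <- mutateSeqs(substring(hap$seq, s, e), lr$errorRate)
        recs <- .walkLongRead(pieces, s, e)
        for (ri in seq_along(recs)) {
          rec <- recs[[ri]]
          cigar <- paste0(rec$lens, rec$ops, collapse = "")
          rows[[length(rows) + 1L]] <- data.frame(
            qname = sprintf("h%d_lr%06d", h, k),
            flag = if (ri == 1L) 0L else 2048L,
            chrom = ref$chrom, pos = rec$pos, mapq = 60L,
            cigar = cigar, mchrom = NA_character_, mpos = 0L, tlen = 0L,
            seq = seq)
        }
      }
      ## ghost-L1 reads: both-side-clipped records on the donor copy
      ghosts <- planted$truth[planted$truth$type == "ghost_l1", ,
                              drop = FALSE]
      if (h == 1L && nrow(ghosts)) {
        for (gi in seq_len(nrow(ghosts))) {
          ev <- ghosts[gi, ]
          insPiece <- pieces[pieces$type == "ins" &
                               !is.na(pieces$eventId) &
                               pieces$eventId == ev$id, , drop = FALSE]
          donor <- ref$fullL1s[ev$donorIdx]
          m <- min(ev$insLen, width(donor))
          for (rk in seq_len(lr$ghostReads)) {
            flA <- sample(800:2000, 1L); flB <- sample(800:2000, 1L)
            s2 <- insPiece$hapStart - flA
            e2 <- insPiece$hapEnd + flB
            seq <- mutateSeqs(substring(hap$seq, s2, e2), lr$errorRate)
            clipR <- flB + (ev$insLen - m)
            rows[[length(rows) + 1L]] <- data.frame(
              qname = sprintf("ghost%d_r%d", ev$id, rk),
              flag = 0L, chrom = ref$chrom, pos = start(donor),
              mapq = 60L,
              cigar = paste0(flA, "S", m, "M", clipR, "S"),
              mchrom = NA_character_, mpos = 0L, tlen = 0L, seq = seq)
          }
        }
      }
    }
    tbl <- do.call(rbind, rows)
    tbl <- tbl[order(tbl$pos), , drop = FALSE]
    rownames(tbl) <- NULL
    alignmentTable(tbl)
  })
}

#' Simulate site-level genotype features
#'
#' Draws the 14-feature vectors directly from the read-support model at a
#' site of known genotype and depth: carrier reads contribute clips and
#' discordant pairs in proportion to the allele fraction, reference reads
#' contribute fully mapped spanning pairs, and reference-homozygous sites
#' carry only sporadic noise support.
#'
#' @param nPerClass Sites per genotype class.
#' @param depth Mean sequencing depth.
#' @param seed Seed.
#' @return list(features = matrix(n x 14), labels = integer vector).
#' @export
simulateGenotypeSites <- function(nPerClass = 300L, depth = 30, seed = 1L) {
  withSeed(seed, {
    one <- function(g) {
      f <- g / 2
      J <- stats::rpois(1L, depth)
      if (g == 0L) {
        clipL <- stats::rpois(1L, 0.15); clipR <- stats::rpois(1L, 0.15)
        disc <- stats::rpois(1L, 0.2)
        spanning <- stats::rbinom(1L, J, 0.9)
        fmL <- spanning + stats::rpois(1L, 1); fmR <- spanning
        polyA <- 0L; tsd <- 0L
        conc <- if (clipL + clipR > 0) stats::runif(1, 0.3, 0.7) else 0
      } else {
        carrier <- stats::rbinom(1L, J, f)
        clipT <- stats::rbinom(1L, carrier, 0.9)
        clipL <- stats::rbinom(1L, clipT, 0.5); clipR <- clipT - clipL
        disc <- stats::rbinom(1L, round(depth * 0.5), f * 0.8)
        spanning <- stats::rbinom(1L, J - carrier, 0.9)
        fmL <- stats::rbinom(1L, J - carrier, 0.9)
        fmR <- stats::rbinom(1L, J - carrier, 0.9)
        polyA <- stats::rbinom(1L, clipT, 0.7)
        tsd <- if (clipT > 0) sample(8:16, 1L) else 0L
        conc <- if (clipT > 0) stats::runif(1, 0.85, 1) else 0
      }
      ratio <- if (disc + spanning > 0) disc / (disc + spanning) else 0
      mapq <- 60 - abs(stats::rnorm(1, 0, 2))
      localDepth <- J + stats::rnorm(1, 0, 1.5)
      c(clipL, clipR, disc, spanning, ratio, fmL, fmR, polyA, tsd,
        mapq, conc, localDepth, clipL / depth, clipR / depth)
    }
    labels <- rep(0:2, each = nPerClass)
    feats <- t(vapply(labels, one, numeric(14)))
    colnames(feats) <- genotypeFeatureNames()
    list(features = feats, labels = labels)
  })
}

#' Simulate trios with Mendelian transmission
#'
#' Parent genotypes are drawn from allele frequency \code{af}; the child
#' genotype transmits one allele from each parent. Site-level features
#' are generated per individual.
#'
#' @param nSites Number of sites.
#' @param depth Mean depth.
#' @param af Alternate-allele frequency (default 0.4).
#' @param seed Seed.
#' @return list(features = list(F, M, C matrices), genotypes =
#'   data.frame(F, M, C)).
#' @export
simulateTrioSites <- function(nSites = 200L, depth = 30, af = 0.4,
                              seed = 1L) {
  withSeed(seed, {
    gparent <- function(n) stats::rbinom(n, 2L, af)
    transmit <- function(g) if (g == 1L) sample(0:1, 1L) else g / 2L
    gF <- gparent(nSites); gM <- gparent(nSites)
    gC <- mapply(function(f, m) transmit(f) + transmit(m), gF, gM)
    innerSeed <- sample.int(1e6, 3L)
    feats <- function(g, sd) {
      ## reuse the site-level model with per-site genotypes
      out <- matrix(0, nrow = length(g), ncol = 14L)
      for (i in seq_along(g)) {
        sdi <- as.integer((as.numeric(sd) * 7919 + i) %% 2147483000)
        tmp <- simulateGenotypeSites(1L, depth, seed = sdi)
        out[i, ] <- tmp$features[match(g[i], tmp$labels), ]
      }
      colnames(out) <- genotypeFeatureNames()
      out
    }
    list(features = list(F = feats(gF, innerSeed[1]),
                         M = feats(gM, innerSeed[2]),
                         C = feats(gC, innerSeed[3])),
         genotypes = data.frame(F = gF, M = gM, C = gC))
  })
}

#' Write truth events as TSV
#' @param truth Truth data.frame from \code{\link{plantInsertions}}.
#' @param path Output path.
#' @export
writeSimTruth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
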