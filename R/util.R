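## Shared small helpers: seeded evaluation, random sequence, polyA runs.

## Evaluate expr with a temporary RNG state; restores the caller's state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Random DNA string of length n under the current RNG state.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Reverse complement for plain character strings.
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## Introduce uniform substitutions into sequences at the given per-base rate.
## Vectorised over a character vector; deterministic under the current RNG.
mutateSeqs <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  if (!length(idx)) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    new <- sample(bases, length(pos), replace = TRUE)
    clash <- new == ch[pos]
    while (any(clash)) {
      new[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- new == ch[pos]
    }
    ch[pos] <- new
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

## Length of the terminal A (or T) run at one end of a sequence, tolerating
## impurity: the longest terminal window with >= minPurity of the base.
terminalPolyRun <- function(seq, base = "A", side = c("right", "left"),
                            minPurity = 0.8) {
  side <- match.arg(side)
  if (is.na(seq) || !nchar(seq)) return(0L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (side == "right") ch <- rev(ch)
  hits <- cumsum(ch == base)
  k <- seq_along(ch)
  good <- which(hits / k >= minPurity)
  if (!length(good)) return(0L)
  n <- max(good)
  ## trim back so the run ends on the base itself
  while (n > 0L && ch[n] != base) n <- n - 1L
  as.integer(n)
}

## Longest pure base-run within the terminal `window` bp of a sequence
## (tolerates a short non-run overhang such as a target-site-duplication
## copy beyond the polyA tail).
windowPolyRun <- function(seq, base = "A", side = c("right", "left"),
                          window = 50L) {
  side <- match.arg(side)
  n <- nchar(seq)
  if (is.na(seq) || n == 0L) return(0L)
  sub <- if (side == "right") substr(seq, max(1L, n - window + 1L), n)
         else substr(seq, 1L, min(n, window))
  ch <- strsplit(sub, "", fixed = TRUE)[[1L]]
  r <- rle(ch == base)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

## PolyA evidence at either terminus of a clipped / inserted segment.
## Returns list(len, side) with side in {left, right, none}; the polyA of a
## plus-strand retroelement appears as an A-run at the segment start or end,
## a minus-strand one as a T-run. Both a purity-tolerant terminal run and
## a windowed pure run (tolerating a short TSD overhang) are considered.
polyASignal <- function(seq, minRun = 5L, minPurity = 0.8) {
  runs <- c(
    right = max(terminalPolyRun(seq, "A", "right", minPurity),
                windowPolyRun(seq, "A", "right")),
    left  = max(terminalPolyRun(seq, "A", "left",  minPurity),
                windowPolyRun(seq, "A", "left")),
    rightT = max(terminalPolyRun(seq, "T", "right", minPurity),
                 windowPolyRun(seq, "T", "right")),
    leftT  = max(terminalPolyRun(seq, "T", "left",  minPurity),
                 windowPolyRun(seq, "T", "left")))
  best <- which.max(runs)
  if (runs[best] >= minRun) {
    side <- c("right", "left", "right", "left")[best]
    list(len = as.integer(runs[best]), side = side)
  } else list(len = 0L, side = "none")
}

## Single-linkage clustering of sorted integer positions with a maximum gap.
## Returns an integer vector of cluster ids (in input order).
gapCluster <- function(pos, maxGap) {
  if (!length(pos)) return(integer(0))
  o <- order(pos)
  p <- pos[o]
  id <- cumsum(c(1L, diff(p) > maxGap))
  out <- integer(length(pos))
  out[o] <- id
  out
}

## Modal value of an integer vector (smallest on ties).
modalValue <- function(x) {
  t <- table(x)
  as.integer(names(t)[which.max(t)])
}
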