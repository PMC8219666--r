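---
title: "retrofind: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retrofind: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Active human retroelements (L1, Alu, SVA) continue to create *nonreference
insertions*: TE copies carried by an individual but absent from the
reference assembly. In coordinate-sorted alignments such an insertion leaves
a characteristic footprint: reads crossing either junction are soft-clipped,
with the clipped bases coming from the inserted element; mates of read
pairs straddling the junction land inside the insertion and fail to map
concordantly; the target site is usually duplicated by a few bases (TSD)
and the element carries a 3' polyA tail. retrofind detects, genotypes and
structurally annotates such insertions from short- and long-read
whole-genome alignments, and ships a deterministic simulator that generates
every input it consumes, so the entire pipeline is validated end to end
without external data.

# Short-read discovery

Discovery is *clip-first*: candidate sites are positions where soft-clipped
read ends stack (within ±3 bp, clip length ≥ 10 bp), rather than clusters of
discordant pairs. Starting from clips preserves sensitivity near other
structural variation and gives base-pair breakpoints directly. Candidate
support thresholds scale with depth:

    minClipReads = minDiscReads = max(2, floor(depth × clonality / 10))

so a 30X germline sample requires 3 supporting clips and a 60X tumor
screened at clonality 0.25 requires 2. The linear depth scaling with a
floor of 2 is this package's quantification; it is monotone in
depth × clonality and configurable.

Every candidate is then profiled on the TE consensus. Clips of
right-clipped reads (the 5' genomic side) form cluster **c1**, clips of
left-clipped reads cluster **c2**; mates of discordant reads anchored on
the 5' side form **d2** and on the 3' side **d1** (all clustered by single
linkage at 50 bp on the consensus coordinate). A two-sided candidate is
accepted when

* each clip category concentrates ≥ 80% of its reads in one cluster
  (the single-breakpoint condition; the 80% figure quantifies "not
  scattered"), and
* |center(c1) − center(d2)| and |center(c2) − center(d1)| are at most
  μ + 3σ of the insert size.

The insert-size gate is applied one-sided (an upper bound only): clip and
mate clusters of a genuine short insertion can be arbitrarily close on the
consensus, so a lower bound would reject real events. Individual
consensus hits must cover ≥ 25 bp at ≥ 80% identity with score ≥ 40 under
the package scoring; looser acceptance lets random genomic sequence (for
example a transduced flank) masquerade as weak consensus support.

Candidates inside a reference repeat of the *same family* with divergence
below 5% (configurable) are removed: young same-family copies are the
dominant source of mismapping artifacts, and the divergence column of the
repeat annotation identifies them.

One-sided candidates are not discarded. If the sequences unexplained by the
consensus align uniquely into the indexed 2 kb 3'-flank window of a
full-length source element, the candidate is a *canonical* transduction
(some support aligned to the consensus) or an *orphan* transduction (none
did). Otherwise a depressed read-depth plateau (mean < 0.6 × flank depth
over ≥ 50 bp) adjacent to the site marks a *target-site deletion*, and the
depth-recovery coordinate becomes the second breakpoint; the echo
candidate that the distal junction's clip stack produces is suppressed in
favor of the insertion-junction call.

TSD and polyA conventions: clip anchors are the last aligned base
(right clips) or the first aligned base minus one (left clips). A TSD
exists when the two anchors differ by 1–50 bp and equals the reference
substring between them. PolyA calls require a run of ≥ 5 A (or T on the
minus strand) at ≥ 0.8 purity at a clip terminus; a windowed variant
(longest pure run within the terminal 50 bp) tolerates the TSD copy that
follows the tail in assembled sequences. The 50 bp TSD cap and the polyA
acceptance values are package choices; none are dictated by the method's
source material beyond "short".

# Long-read discovery

Long reads clip at variable positions, so clip anchors and CIGAR
insertion operations (`I` ≥ 100 bp; terminal clips ≥ 30 bp) are grouped by
single linkage at 75 bp, and a group is rejected when the RMS distance of
anchors from the median anchor exceeds 45 bp. The RMS-from-median reading
of "standard deviation of the distance to the median" reproduces the
worked example used in the tests (anchors 1000/1005/1010 give 4.08).

Supporting reads are assembled by a built-in backbone-and-polish
assembler: the longest junction-local read subsequence is the backbone,
remaining reads extend it when their overhang reaches past either end
(overlap ≥ 200 bp at ≥ 70% identity), and a per-column majority vote
corrects substitution errors. Assembly is deterministic (reads processed
in (length, sequence) order) and therefore invariant to read permutation;
it fails when fewer than half of the non-backbone reads align, which is
the signal for mutually unalignable read sets. The assembler is a
contract: an external assembler can be substituted without changing any
caller. Only the 5 longest reads per site are assembled — deeper clusters
carry redundant evidence, and junction-local trimming (segment ± 1.5 kb)
keeps the dynamic programming quadratic in the insertion length rather
than the read length.

The reference flanks of the site (500 bp each) are aligned to the contig;
when both align at ≥ 80% identity over ≥ 80% of their length and are
separated by ≥ 50 bp, the contig sequence strictly between the flank hits
is the insertion, and the inner flank edges replace the cluster median as
the breakpoints. The 500/80/80/50 values are package choices for "well
aligned but far apart". The insertion is then classified against the
consensus library; residual unaligned segments ≥ 50 bp feed transduction
tracing (unique flank-window hit at ≥ 90% identity; a second window within
90% of the best score makes the hit ambiguous) and the pseudogene scan.

Hybrid mode merges short-read and long-read candidates within 50 bp,
keeping the long-read breakpoints and assembled sequence and carrying
over short-read-only mechanistic evidence (TSD).

# Genotyping

Fourteen features summarize the read support at a call site (order fixed,
versioned in serialized models): left/right clip counts, discordant count,
concordant-spanning count, discordant/(discordant+concordant) ratio,
fully-mapped read counts at each breakpoint, polyA-supporting clip count,
TSD length, mean MAPQ of supporting reads, clip-position concordance,
local depth, and the two clip counts normalized by mean depth. Training
labels come from trio evidence rules: heterozygous when exactly one parent
carries the call and the other has no supporting clips; reference
homozygous when neither parent has clips; alternate homozygous when both
parents carry it, the discordant ratio strictly exceeds 0.85 and no fully
mapped reads cross the breakpoints. Sites matching no rule are excluded
rather than defaulted. The classifier is a seeded 200-tree random forest
with a stratified 70/30 split.

Pedigree quality control uses the biallelic Mendelian model: a child
genotype is consistent iff it is reachable by transmitting one allele from
each parent; 12 of the 27 trio genotype combinations are inconsistent.

# Somatic mode

Case calls are screened against the matched control: supporting clips
within ±10 bp plus discordant pairs are counted, and a call is *somatic*
when that support is at most `max(1, floor(controlDepth / 30))`,
*germline* above three times that allowance, and *ambiguous* between (or
when control coverage is < 5X). The allowance formula and the 3× band
quantify "no or few supporting reads, adjusted by depth" and are
configurable. Tumor purity enters through the clonality factor of the
calling thresholds; because thresholds are monotone in clonality,
lowering clonality can only add calls on fixed data.

# Structural annotation

**L1 internal structure.** The insertion is split-aligned onto the L1
consensus. An affine aligner bridges an internal deletion as one alignment
containing a long consensus gap, so the primary alignment is split at
internal query-gap runs strictly greater than 20 bp; an unaligned terminal
segment is realigned separately and an opposite-orientation part marks a
twin-priming inversion. Categories — full length (≥ 95% consensus
coverage), 5'-truncated, internal deletion (gap > 20 bp, strict), internal
inversion, deletion-and-inversion — are mutually exclusive.

**Processed pseudogenes.** After stripping the terminal polyA/T tail, at
least two exons of a single gene must tile ≥ 80% of the insertion in
transcript order with ≤ 20 bp between consecutive exon hits, and each hit
must be unique: a mapping-quality equivalent, computed from the score
margin over the best competing exon hit on the same region, must reach 30.
A duplicated (paralogous) exon therefore contributes nothing.

**Ghost L1s.** Reads aligning to a reference full-length L1 donor with
clips on *both* flanks carry the true flanking sequence of a nonreference
copy. Clipped flanks are all-vs-all aligned and clustered by single
linkage at ≥ 85% identity over ≥ 200 bp (minimum cluster size 2); each
cluster's flanks are assembled and classified, and the cluster is reported
iff a flank is Alpha, Beta or HSATII satellite. Only full-length donors
are scanned, which favors specificity.

**TE-mediated SVs.** Breakpoints are paired by the reciprocal condition
(the reference flank of each breakpoint aligns into the clipped-side
contig of the other); junctions observed inside single spanning alignments
(an insertion operation adjacent to a ≥ 100 bp deletion operation) are
handled directly. For each pair, the contig between the outer reference
flanks is decomposed: fully-TE internal sequence with a flank gap ≥ 100 bp
(beyond TSD scale) is a deletion; a residual aligning the reference in
opposite orientation between the flanks is an inversion; residuals from
both sides of the TE aligning the same reference interval are a
duplication.

**Dimorphic HERVs.** At each solo-LTR locus, boundary evidence is
assembled; the reference flanks outside the LTR delimit the candidate
copy; the LTR consensus must align to both candidate ends and the middle
must classify as HERV (coverage gate relaxed to 25% because internal
deletions fragment the alignment). The internal deletion length is the
HERV-internal consensus length minus the observed middle when the
difference exceeds 100 bp.

# The simulator

The generator builds a miniature genome (single chromosome) with diverged
Alu/L1 background copies, full-length L1 sources with unique indexed 2 kb
downstream flanks, satellite blocks (tandem arrays at ~8% per-copy
divergence), solo LTRs and a small gene set, all recorded in a
RepeatMasker-style annotation. Events of every supported class are planted
with ≥ 10 kb spacing, TSDs of 5–20 bp and polyA tails of 10–40 bp where
mechanistically appropriate. Alignments are emitted *analytically* from
the event coordinates — no external aligner — so clip and CIGAR signatures
are exact and error injection (after alignment computation) cannot distort
them.

Deliberate idealizations, and what they imply about test results:

* Errors are substitutions only; real long-read error is indel-dominated.
  Passing tests show the pipeline's logic is correct, not that it is
  robust to homopolymer indels.
* Short-read sequences are materialized only where sequence-level
  evidence is consumed (clipped and unmapped reads).
* Satellite blocks are excluded from ordinary read sampling (they are
  unmappable in practice); ghost-L1 reads are emitted separately as
  donor-mapped both-side-clipped records, mirroring how such reads align
  in real data. Event placement keeps other events ≥ 16 kb away from
  satellite blocks so ordinary reads never straddle excluded sequence.
* All mapped reads carry MAPQ 60 and there are no duplicates, so the
  MAPQ/duplicate filters are exercised by constructed fixtures rather
  than the scenarios.
* Genotype-classifier validation uses a site-level support model
  (binomial draws of clip/discordant/spanning counts given the allele
  fraction) rather than full pileups, which keeps 960-site training sets
  affordable; feature extraction from alignments is validated separately
  on called sites.

Study conditions: the short-read scenario uses a 2 Mb genome, 30 planted
events across all insertion classes at 30X (150 bp reads, 500 ± 50 bp
inserts, 0.2% error); the long-read scenario 1 Mb, 20 events at 20X
(12 ± 2 kb reads, 1% error); somatic validation 900 kb with 10 somatic +
10 germline events at 60X/30X error-free; annotation scenarios 400–700 kb.
These sizes were chosen so each scenario represents its full event
spectrum while a complete validation run stays in the tens of minutes on
a single core.

# Numerical choices and degenerate inputs

Alignment uses fixed scoring (match +2, mismatch −4, gap open −4, extend
−2) with deterministic tie-breaks (lower target start, then + orientation),
so all downstream results are reproducible; the contract requires only a
best local alignment, not a reproduction of any particular aligner.
Insert-size moments discard fragments beyond the 99.5th percentile before
computing μ and σ; fewer than 100 proper pairs is an error because the
±3σ gate cannot be calibrated. Interval arithmetic is 1-based inclusive
throughout, matching the native interval containers; conversion happens
only at I/O boundaries (RepeatMasker `.out` 1-based in, VCF 1-based out,
BED 0-based half-open out). Empty inputs yield empty call sets; a
zero-coverage genotyping site yields the all-zero (0/0-like) feature
vector; candidates whose sequences align to no consensus are routed to
the transduction/target-site-deletion path rather than rejected.

# Known limitations

* The surrogate repeat classifier is not RepeatMasker; its 80/50
  identity/coverage acceptance is a package choice, and subfamily
  assignment between close subfamilies (AluYa5 vs AluYb8) depends on a
  handful of diagnostic positions.
* The built-in assembler corrects substitutions only and does not
  phase; haplotype-resolved assembly is out of scope.
* Breakpoint refinement reports the flank inner edges; with a TSD the
  right flank aligns beyond the duplicated bases, so long-read TSD
  lengths are approximate (hybrid merging carries exact short-read TSDs).
* 10X Linked-Read support is deliberately absent.
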