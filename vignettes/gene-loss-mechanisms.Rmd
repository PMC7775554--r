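---
title: "Distinguishing excision from pseudogenization in synteny blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing excision from pseudogenization in synteny blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracsig)
```

## The question and the measurement

After a whole-genome duplication (WGD), or after speciation splits one gene
complement into two independently evolving copies, most duplicate gene pairs
eventually lose one member. Two mechanisms could explain a missing copy:

* **excision** — the DNA segment containing the gene (or a run of genes) is
  physically deleted, creating a new adjacency and leaving at most a short
  non-coding residue;
* **pseudogenization** — a stop codon or frameshift silences the gene; its
  annotation disappears, but the DNA initially stays in place.

Synteny blocks make the two distinguishable. Inside a block — a run of
homologous gene pairs in conserved order on two homeologous regions — a
*deletion interval* is a gap between consecutive anchor pairs where one side
(the *unfractionated* side) still carries `L` contiguous single-copy genes
while the other (the *fractionated* side) carries none that the homology
search can see. The package measures, for every interval, the DNA span
between the bounding anchor genes on both sides. Plotting span against `L`:

* the unfractionated span must grow linearly, with slope equal to the local
  mean gene-plus-intergenic size — the inverse of the gene density;
* under excision the fractionated span is flat in `L`, near the per-event
  residue;
* under pseudogenization the fractionated span grows like the
  unfractionated one, since the silenced genes' DNA is retained.

An ordinary least-squares fit on each side and a Welch t-test on the slope
difference turn this contrast into a statistic. A complementary
*pseudogene capacity*, the fractionated span divided by the mean gene
length, bounds from above the number of full-length pseudogenes an interval
could conceal.

## Pipeline stages and their parameters

1. **Annotations** (`readGff3()`, `readBed()`): gene-level features only.
   Internally all coordinates are 0-based half-open; 1-based GFF3 input is
   converted at the boundary, so span arithmetic is convention-free
   everywhere else. Within a chromosome, gene ranks `0..n-1` follow start
   coordinates, with ties broken by end coordinate and then gene id — an
   arbitrary but fixed order that makes interval scanning deterministic for
   overlapping gene models. Strand is carried but never used: the method
   measures raw DNA amounts.

2. **Anchor pairs and the similarity window** (`readAnchorPairs()`,
   `selectSimilarityWindow()`): each anchor pair carries a percent identity.
   The distribution of similarities is multimodal when several duplication
   cohorts coexist; the analysis must isolate blocks created by the most
   recent event. The automatic policy smooths the per-percent histogram with
   a centered 3-bin moving average, takes the local mode at the *greatest*
   similarity (the youngest cohort) and extends the window to the flanking
   local minima. Smoothing suppresses single-bin sampling wiggles that would
   otherwise stop the walk early; edge bins are not accepted as modes, so a
   monotone histogram raises an error directing the user to manual bounds
   rather than inventing a cohort. The window filters *block mean*
   similarity only — individual pairs are never dropped from a retained
   block.

3. **Chaining** (`chainAnchors()`): within each chromosome pair, anchors are
   points in (rank~A~, rank~B~) space and blocks are collinear chains,
   strictly increasing in rank on side A and strictly monotone on side B
   (increasing = `same`, decreasing = `inverted` orientation — inversions
   would otherwise fracture every block they touch). Consecutive anchors may
   skip at most `maxGap` genes on either side; the gap is measured in gene
   ranks, not base pairs, so that interval lengths in genes are exact. The
   default `maxGap = 20` is deliberately permissive: runs of lost genes
   appear as rank gaps of `L + 1` on the unfractionated side, and the gap
   cap is what ultimately truncates the observable `L` range. Blocks are
   extracted by iterated peeling of the best remaining chain (dynamic
   programming, score = anchor count). Ties are resolved totally: smallest
   start rank on side A first, then the lexicographically smallest anchor
   sequence, with `same` orientation preferred over `inverted` on exact
   ties. Peeling scores never increase, so the block list at a stricter
   minimum block size is a prefix of the list at a looser one — which makes
   the threshold sensitivity sweep (`blockSizeSensitivity()`) exact from a
   single chaining pass. The minimum block size defaults to 5 anchors; the
   sweep over 3–6 shows why: at 3 the chaining starts to absorb
   coincidentally neighboring independent duplicates.

4. **Interval scanning** (`scanDeletionIntervals()`): for each pair of
   consecutive anchors in a retained block, the genes strictly between them
   are counted on both sides. The clean and overwhelmingly common case is
   genes on exactly one side: an interval of length `L` (all annotated genes
   on the unfractionated side) with the other side empty. When *both* sides
   carry annotated genes the scan demands positive evidence before calling a
   side fractionated: the unfractionated side must contain at least one
   anchor-participating gene while the other side contains none. Annotated
   but never-paired genes on the fractionated side — genes a homology screen
   cannot vouch for — do not disqualify the interval; they are counted in
   `nonanchor_genes_in_gap`, and `strict = TRUE` excludes such intervals for
   a sensitivity check. Gaps with unpaired genes on both sides are
   ambiguous (they are exactly what two adjacent opposite-side loss runs
   produce) and emit nothing.

5. **Spans** (`measureSpans()`): on each side, the span runs from the end of
   the positionally earlier bounding gene to the start of the later one,
   after ordering the two bounding genes by coordinate — which also handles
   inverted blocks, where chain order and coordinate order disagree on side
   B. An alternative midpoint-to-midpoint convention is available
   (`spanMode = "midpoint"`). Overlapping bounding gene models produce a
   negative raw span; it is clamped to zero and flagged rather than
   propagated.

6. **Regressions** (`fitLinear()`, `compareSlopes()`): the default fits every
   interval as one point (`mode = "raw"`), which gives standard errors that
   reflect the true interval count; `mode = "length_means"` fits the per-`L`
   means, the quantity classically plotted. Lengths beyond `lCap` (default
   30 genes) are excluded from fits: long intervals are rare and their means
   fluctuate accordingly, while the points remain available in the profile.
   The slope test uses unpooled (Welch) variances with Satterthwaite
   degrees of freedom — the two sides have grossly unequal scatter, so a
   pooled test would be anti-conservative. Zero standard errors are handled
   explicitly: identical slopes give `t = 0, p = 1`; different slopes with
   zero SEs are flagged degenerate. No multiple-testing correction is
   applied across genome pairs; each comparison is an independent headline
   analysis.

7. **Density diagonal** (`densityComparison()`): per genome, the bp-per-gene
   of the conserved intervals is paired with the genome-wide
   `total_bp / gene_count`. The default estimator is the regression slope,
   which *is* the inverse density of the intervals; the raw ratio
   `sum(bp) / sum(L)` is also provided but carries a fencepost bias — an
   interval of `L` genes spans `L + 1` intergenic stretches, so the ratio
   sits one boundary stretch per interval above the density, noticeably so
   when typical `L` is small. Both estimators are exposed; the worked
   single-interval example in the tests uses the ratio, the diagonal check
   uses the slope.

8. **Translocation audit** (`collectSingletons()`, `findRemotePartners()`):
   if the "missing" genes had actually moved elsewhere rather than being
   deleted, the surviving singletons would pair with remote partners at
   roughly the event cohort's similarity. The audit takes the raw anchor
   list (the minimum-block-size-1 view), counts singletons with any partner
   inside the cohort window, and reports the rounded percentage. The count
   is an upper bound on translocation: pre-existing paralog triplets also
   produce in-window hits and are not deconvolved.

## The synthetic genome pair generator

Real genome downloads are replaced by a forward simulator
(`simulateGenomePair()`) whose defaults mirror a mid-size plant genome:
10,000 ancestral genes on 5 chromosomes, lognormal gene lengths of mean
3 kbp and intergenic stretches of mean 5 kbp (sigma 0.25 on the log scale),
a 30% pair-loss fraction in runs of geometric mean length 2, and a 400 bp
mean excision residue. The event is either speciation (two sister gene
tables) or WGD (one doubled table analyzed as a self-comparison).

Choices that matter scientifically:

* **Excision removes the whole stretch between the surviving neighbour
  genes**, intergenic DNA included, and leaves a single exponential residue
  *per event*, not per gene. This is precisely the mechanism under test:
  it is what makes the fractionated span flat in `L` with an intercept near
  the residual mean. A later excision adjacent to an earlier one swallows
  the earlier residue, as a physical deletion would.
* **Pseudogenization deletes the annotation and its anchor but no DNA**, so
  chromosome lengths are conserved exactly and the fractionated span tracks
  the unfractionated one.
* **At most one member per pair is ever lost** — the scan needs surviving
  singletons, and a doubly-deleted pair is invisible to any synteny method.
  Loss runs are placed uniformly at random over intact pairs and truncate
  at chromosome ends and previously touched pairs; a renewal-process
  placement was not needed for any property tested here.
* **Similarity cohorts**: recent pairs draw from a truncated normal
  (default mean 92%, sd 2), an optional older cohort (default 75%, sd 3) is
  attached to duplicated remote segments so that it forms its own collinear
  blocks, as an older WGD would. Noise anchors — duplications unrelated to
  the event that happen to sit near each other — are drawn in small
  clusters of 2–4 pairs within a few ranks of a shared center; isolated
  uniform pairs on a genome-sized rank grid would practically never be
  "coincidentally neighboring", and it is these clusters that a permissive
  block-size threshold of 3 starts to absorb.
* **Rearrangements**: inversions reflect a run of genes in place (strand
  flipped, lengths and internal gaps preserved); translocations move one
  member of an intact pair, DNA included, to a random remote insertion
  point, leaving its anchor in the pair list — the configuration the
  translocation audit is designed to detect.
* **Ground truth**: every mutation is executed by a parameter-explicit
  primitive and logged; `replayTruthLog()` folds the log over the ancestor
  and must reproduce the emitted genomes byte-exactly. The log also yields
  the expected interval set against which the scanner is tested.

What the simulator does **not** emulate: nucleotide sequence (and hence
real percent-identity estimation), transposable-element dynamics and other
repetitive-DNA growth, gene-density inhomogeneity along chromosomes,
within-block similarity autocorrelation, and post-loss residue decay over
time. Passing tests therefore demonstrate that the measurement recovers the
mechanisms under the stated generative model, not that any particular real
genome pair is fractionating by excision; on real data the similarity
window in particular may need the manual policy, and repetitive-sequence
accumulation can inflate fractionated spans independently of
pseudogenization (the normalization by the genome-size factor,
`genomeSizeFactor()`, is the first-order correction for exactly that).

A deliberately asymmetric scenario (`intergenic_scale_b`) inflates genome
B's intergenic stretches by a constant factor, emulating a partner genome
bloated by repetitive DNA; dividing its spans by the bp-per-gene ratio of
the two genomes brings the two conserved slopes back together, which is the
normalization property checked in the acceptance suite.

## Numerical and degenerate-input policy

* Interval spans are kept as plain doubles (exact for genomic magnitudes);
  normalization divides spans, and applying a factor and its inverse is an
  exact identity.
* Perfectly collinear fit inputs (an exact line) are legal; the fit suppresses
  the "perfect fit" warning and reports `r_squared = 1`.
* `fitLinear()` refuses fewer than 3 points or a single distinct `L`;
  `findRemotePartners()` refuses an empty singleton set (the percentage is
  undefined); `summarizeGenome()` refuses zero genes and missing
  chromosomes.
* Empty annotation files parse to empty tables; empty anchor sets produce
  empty histograms and zero sensitivity counts.
* All randomness in the simulator flows from the single `seed` in
  `simConfig()`; emitted fixture files are byte-stable, and the pipeline
  itself draws no random numbers, so reports and artifacts are
  reproducible byte for byte.

## Problem sizes used in the checks

The packaged checks run the full study conditions — 10,000 duplicate pairs
per fixture, three seeds for the excision scenario — for the acceptance
properties, and reduced 2,000–3,000-gene versions of the same conditions
for the unit-level properties, where the contrasts are already far from
their thresholds. The chaining oracle (exhaustive enumeration of maximal
collinear chains) is compared on fifty random instances of up to 50 genes
per side, small enough for the exponential enumeration to stay instant.

## Known limitations

* The interval definition cannot distinguish an annotated-but-unpaired gene
  relic on the fractionated side from an assembly/annotation artifact; the
  `nonanchor_genes_in_gap` tally and `strict` mode expose, but do not
  resolve, the confound.
* Blocks are never merged across rearrangement breakpoints, so heavy
  rearrangement shortens blocks and discards boundary intervals rather than
  mis-measuring them.
* Ks-based cohort dating is out of scope; percent identity is taken as
  given. A Ks column can be used by inverting the window bounds manually.
* The audit counts remote partners, not mechanisms: retrotransposed copies
  and ancient paralogs inflate it, which is why it is read as an upper
  bound.
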