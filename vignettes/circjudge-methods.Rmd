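---
title: "Recognizing true circRNAs from RNA-seq alignments: methods and design"
author: "circjudge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing true circRNAs from RNA-seq alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Back-splicing joins a downstream splice donor to an upstream acceptor and
produces a covalently closed circular RNA (circRNA). In RNA-seq aligned to
a linear reference, the only direct evidence for a circle is the
back-spliced junction (BSJ): reads crossing it align as clipped segments
in reversed genomic order. The same clipped-alignment signals, however,
are produced by sequencing errors, repeats and ambiguous mapping, so
detectors tuned for sensitivity emit many false candidates. `circjudge`
treats the final call as a supervised classification problem: collect a
permissive candidate set, describe each candidate with a 23-dimensional
feature vector computed from the alignments and the reference, and let a
gradient-boosted decision-tree (GBDT) ensemble separate real circles from
artifacts.

## Candidate collection from PSS signals

A circle `[brk1, brk2]` (1-based, inclusive; all internal coordinates are
SAM-native, BED input is converted at the I/O boundary) leaves two
clipped-read populations:

* upstream reads with CIGAR `xS yM` whose match starts at `brk1` — the
  clip is the sequence just inside `brk2`;
* downstream reads with CIGAR `yM zS` whose match ends at `brk2` — the
  clip is the sequence just inside `brk1`.

A pair of such reads whose clipped portions are locally similar to the
partner's matched flank is a *paired similar sequence* (PSS) signal.
Because both the upstream clip and the downstream matched block end
exactly at `brk2` (and symmetrically at `brk1`), the scan first gates
position pairs with exact 10-mer terminal seeds — one error-free seed
among the supporting reads suffices — and then verifies each read pair
with a gap-free overlap identity (`local_similarity()`), requiring at
least 0.90. The threshold is not part of the published description of the
signal, which only calls it "locally similar"; 0.90 tolerates roughly one
error per 10 bp at typical sequencing error rates. Forward-splice (FSJ)
clipped reads at ordinary exon junctions are rejected twice over: their
clip content does not match the candidate flank, and their implied
breakpoints are in forward order (`brk2 < brk1`), which the scan never
pairs.

A PSS pair becomes a candidate only if the records' strands agree, each
junction read's mate maps inside `[brk1, brk2]` (every read of a circular
fragment stays inside the circle), and the span is 100 bp – 50 kb.
Near-duplicate candidates (both breakpoints within 2 bp) are merged into
support-weighted modal breakpoints; 2 bp matches the tolerance used for
the splice-signal search and split-read assignment, keeping all
breakpoint fuzziness rules consistent.

Three-segment (`xS yM zS`) reads can serve either side; clips shorter
than 19 bp are ignored throughout because a default-parameter local
aligner does not seed alignments from shorter segments, so such clips
carry no reliable breakpoint evidence. Soft and hard clips are treated
identically for pattern classification; hard-clipped records lack the
clipped bases and therefore count for support but cannot enter similarity
comparisons.

## The 23 features

For the library insert-size model, the mean `m` and standard deviation
`v` are estimated from |TLEN| of primary, properly-paired, fully aligned
records (up to 100,000 pairs, 1% two-sided trim with a normal-consistency
correction for the scale — chimeric and junction-spanning pairs would
otherwise inflate `v`). Two derived constants recur: the search window
`range = m + 3v` and the discordance threshold `m + 3v`.

Per candidate the feature vector is, in fixed order:

1. **Insert-size features** (4): concordant/discordant pair counts in
   `[brk − range, brk + range]` at each breakpoint. A pair is discordant
   when |TLEN| exceeds `m + 3v` or its mates map to different
   chromosomes; inter-chromosomal pairs cannot be concordant under any
   insert-size rule. Pairs are counted once via the first-in-pair primary
   record, and the pair is assigned to a window by its leftmost mate
   (configurable; the alternative of requiring both mates in-window is
   stricter but was not adopted). Unusually *small* inserts are not
   counted as discordant: small circles can compress apparent inserts,
   but the discordance rule is deliberately one-sided, matching its
   standard definition.
2. **Depth and coverage features** (8): mean per-position read depth and
   mean per-position aligned-base count over the windows `[b − W, b − 1]`
   (Up) and `[b, b + W − 1]` (Down) at each breakpoint, with
   `W = min(range, circle length)` so Down windows never overrun short
   circles. Depth counts primary alignments only; coverage also counts
   supplementary records, mirroring the two common per-base counting
   conventions — this keeps the two feature groups non-redundant, and
   `cov >= depth` always holds.
3. **Split-read features** (6): counts of SM / MS / SMS CIGAR patterns
   assigned to a breakpoint when the match boundary falls within 2 bp of
   it. A read contributes to both breakpoints only when its pattern is
   SMS.
4. **Splice signal** (1): 1 if `AG` immediately precedes `brk1` and `GT`
   immediately follows `brk2` (or the reverse-complement arrangement
   `AC`/`CT`), searching shifts of up to ±2 bp independently at each
   boundary because breakpoints from clipped alignments are only
   approximate. Candidates are *not* filtered on this signal — many real
   circles lack an exact canonical site after alignment fuzz — it is one
   feature among 23.
5. **Junction support** (4): the per-side BSJ support counts and their
   mean mapping qualities (0 when a side is empty). For imported
   candidates without support sets, support is reconstructed from
   clipped reads at the breakpoints.

Feature extraction is deterministic and order-independent: shuffling the
alignment rows leaves the vector unchanged.

## The classifier

`circ_gbdt()` fits a stagewise additive ensemble of regression trees to
the binomial deviance: at iteration *t* each tree fits the
gradient/curvature of the loss under the model of iteration *t − 1*
(leaf values are regularized Newton steps, clamped to ±4 for numerical
stability), and is added with a shrinkage factor. The initial model is
the 0.5 prior, so an ensemble of zero trees predicts 0.5 everywhere, and
hard labels use the 0.5 threshold. Row subsampling per tree (stochastic
gradient boosting) is available through `subsample`; all stochastic paths
derive from one seed, so training is exactly reproducible.

Features are standardized (center/population-spread; constant columns
pass through) before training. Trees are invariant to monotone feature
scaling, so this changes no prediction — the step exists so exported
tables and serialized models carry documented, comparable scales, and a
regression test asserts the invariance. Models serialize to versioned
JSON (trees, scaling, hyperparameters and the feature-name fingerprint);
prediction refuses feature tables whose column fingerprint differs,
preventing silent column swaps.

`grid_search_cv()` performs stratified k-fold cross-validation over a
hyperparameter grid (default: trees 100/300, learning rate 0.05/0.1,
depth 3/5, subsample 0.8/1.0 — a deliberately small desk-scale grid) and
selects the highest mean F1, breaking ties toward fewer trees, then lower
depth. Rows are put in a canonical order before fold assignment so the
selection ignores input order; scaling is refit on each training split.
The published procedure names grid search with 10-fold cross-validation
but neither the grid nor the loss; binomial deviance and this grid are
this package's choices. Likewise, the phrase "random trees kernel" in the
source method's description has no GBDT counterpart; it is interpreted
here as per-tree subsampling.

## The simulator

`simulate_dataset()` generates the study conditions used throughout the
package's benchmarks without any downloads: a uniform-random genome
(default 1 Mb) carrying 200 non-overlapping plus-strand genes of 2–4
exons (exons 300–1200 bp, introns 100–600 bp); 20% of genes also emit a
circRNA over a contiguous exon subset, so circles share exons with their
linear hosts, and 90% of circles get canonical `AG|circle|GT`
dinucleotides planted at their genomic boundaries. Fragments are drawn
per transcript with Poisson pair counts `L * coverage / (2 * read
length)` and insert sizes `N(300, 30^2)` truncated to
`[read length, m + 5v]`; circular transcripts wrap across the junction.
Reads are emitted as *analytic alignments* (no external aligner): each
read's transcript interval is mapped through the exon structure, the
longest segment becomes the primary record and other segments of at
least 19 bp become supplementary records, which reproduces the SM / MS /
SMS clip patterns at circle boundaries exactly as a local aligner
produces them. Substitution errors are applied at 1% per base; TLEN is
the genomic outer span of the primary alignments, and the proper-pair
flag is set only for contiguous fragments, which is what makes
insert-size estimation recover the configured library.

Exon sizes were chosen large relative to the insert so that fragments
contained in a single exon — the estimator's sampling frame — are
representative of the configured insert distribution; with much shorter
exons, conditioning on single-exon placement visibly tilts the estimate.

Decoy artifacts model the error sources that produce false candidates in
real data, at a default rate of 60 events per Mb scaled by
`linear_coverage / 10` (artifacts are produced by reads): (a) randomly
clipped reads whose clip content is random sequence (rejected by the
similarity gate, background for the split-read features), (b)
copied-repeat read pairs that reproduce full PSS geometry at a locus
with no circle — clip content copied from the partner flank, mates
placed inside the fake circle, low mapping quality (0–25) and support
1–2 — these pass candidate collection and are what the classifier must
remove, and (c) low-quality chimeric pairs with inflated template
lengths. The taxonomy is this package's construction; only the error
sources themselves are taken from the literature.

What the simulator deliberately does not model: minus-strand
transcription (all genes are plus-strand; the reverse-complement branch
of the splice-signal check is exercised by hand-built fixtures),
expression-level variation across transcripts (uniform coverage per
class), intron retention, alternative back-splicing isoforms, indel
errors, quality-score structure, multi-mapping ambiguity beyond the
decoy classes, and RNase-R library chemistry (the enrichment labelling
criteria are implemented on junction-read counts instead). Passing the
simulation benchmarks therefore shows the machinery is correct and the
feature/classifier design sound under clean, known conditions — not that
real-data performance will match the simulated numbers.

Everything is a pure function of the configuration: the same config and
seed reproduce byte-identical SAM and truth tables.

## Evaluation

Predicted-positive candidates are matched one-to-one to truth circles
(both breakpoints within ±2 bp, greedily by breakpoint distance so a
truth circle can never yield two true positives — the published
evaluation used an unspecified custom script, and one-to-one matching is
the conservative choice). Sensitivity, precision and F1 follow their
standard definitions, with zero denominators mapped to 0 with a warning,
and FDR reported as 1 − precision. For real-data style benchmarking,
`rnase_r_label()` implements the enrichment criteria: candidates with
fewer than 3 untreated junction reads are excluded, at least 3-fold
enrichment after RNase R treatment is a true positive, and depletion or
disappearance is a false positive. Enrichment between 1× and 3× is not
covered by those two rules; the package labels the gap false-positive by
default and exposes the policy as an option.

## Benchmarks and problem sizes

`detection_benchmark()` re-runs the package's two simulation studies at
desk scale: a ~1 Mb genome with 200 genes and 40 circles per dataset,
(1) 100 bp reads with circle coverage 10× and linear coverage 10/30/50×,
scored with a classifier trained on an independent labelled replicate
simulated at 30× linear coverage, and (2) 150 bp reads at 10×/10× with
its own independent training replicate. These sizes complete in a few
minutes on a single CPU while keeping ≥40 positive and dozens of negative
candidates per dataset, enough for stable precision estimates at the
percent level. The acceptance script (`scripts/acceptance.R`) reports the
headline numbers of these runs; the test suite asserts the same
quantities at fixed seeds.

Numerical conventions worth knowing: split gains must exceed `1e-12` to
be accepted (ties break to the lowest feature index, then the lowest
threshold, making tree construction fully deterministic); leaf values are
clamped to ±4; hessians are floored at `1e-6`; the insert-size trim is
1% per side with the truncated-normal scale correction; all random
streams derive from one integer seed via fixed offsets, and every derived
seed stays below 2^31.

## Known limitations

* Candidate discovery needs both an SM and an MS record per junction, so
  circles supported only by reads whose shorter junction segment is
  under 19 bp are invisible — at 60 bp read length this removes a
  substantial fraction of junction reads, and recall drops accordingly,
  consistent with the general difficulty of short-read circRNA
  detection.
* The classifier is only as good as its training conditions; a model
  trained on the simulator's decoy taxonomy should be retrained (the
  `label` column of a feature table plus `circ_gbdt()` is all that is
  needed) before being trusted on a new library preparation.
* Trans-chromosomal (fusion) circles, annotation-guided candidate
  generation and CRAM input are out of scope.
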