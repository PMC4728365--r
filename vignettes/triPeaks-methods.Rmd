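---
title: "Methods: multi-caller consensus analysis of occupancy ChIP-seq"
author: "triPeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-caller consensus analysis of occupancy ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triPeaks)
```

# Scope and data model

`triPeaks` analyses occupancy of a chromatin protein with weak sequence
specificity from aligned single-end ChIP-seq tags. Its inputs are plain
text: tag BED6 files (treatment and input control), a chromosome sizes
table, a six-column gene table, feature-track BED files, a FASTA genome
and MEME-minimal motifs. Internally every interval lives in a
`GRanges` using the Bioconductor 1-based closed convention; BED's
0-based half-open coordinates are converted only in the readers and
writers, and all overlap logic ("coincident" = at least one shared
base, book-ended intervals merge at gap 0, nearest-point ties break
toward the smaller coordinate) is therefore stated once and tested once.

# The three callers

All callers consume the same `CallerParams`: fragment length `d`
(estimated, fallback 150 bp), window `w = 300` bp for the Poisson and
threshold callers, net-count granularity 20 bp for the strand-transition
caller, Poisson cutoff `1e-5`, fold cutoff `E = 2`, minimum supporting
tags `R = 10`, and minimum run `m = 50` bp. These defaults follow, in
spirit, the published defaults of the model-based and strand-based
callers this trio simplifies; none is fitted to data.

## Fragment-length estimation

The sonication protocol being emulated produces 500–1000 bp fragments
sequenced as 36-base tags from one randomly chosen end. A forward tag's
5' end marks a fragment start and a reverse tag's 5' end marks a
fragment end, so the Pearson correlation between the two 5'-end
densities, as a function of the shift applied to the reverse density,
peaks at the fragment length. We correlate densities counted in 5-bp
bins (which sets the shift resolution and keeps single-base sparsity
from drowning the signal at realistic depths) over shifts 0–1000 bp. A
maximal correlation below 0.1 flags data without strand structure
(e.g. uniform tags) and the estimate is reported as unreliable. Note
that correlating full tag *coverage* instead of 5'-end densities would
peak at `fragment − readlength` and systematically underestimate `d`;
the 5'-end convention is what makes "d ≈ fragment length" true, and is
what the other callers assume when they shift tags by `d/2` or extend
them to `d`.

## Poisson local-background caller

Tags are shifted by `d/2` toward their 3' end, counted in `w`-wide
windows stepping `w/2`, and a window is significant when its count
exceeds a Poisson background at the cutoff. The background rate is
`λ_local = max(λ_genome, λ_5kb, λ_10kb)`, the larger windows computed
from control counts centred on the window and all scaled by the
treatment/control depth ratio. Taking the maximum makes the caller
conservative wherever the *control itself* is locally enriched — the
copy-number-gain case — at the price of slightly reduced power at true
sites on amplified segments. A 1 kb control window is deliberately not
used: at desk-scale control depths (tenths of a tag per kb) its counts
are Poisson noise that the depth ratio would amplify. Overlapping
significant windows merge into one peak; the score is −log10 of the
best window p-value and the summit the position of maximal shifted-tag
coverage.

## Strand-transition caller

A true binding site shows forward tags accumulating upstream and
reverse tags downstream. Net counts (forward − reverse) are formed in
20-bp bins; bins with zero net count carry no direction and are
skipped, and each sign change from positive to negative between
successive direction-carrying bins yields a candidate site at their
midpoint. Retention requires at least `R` treatment tags within
±`flank` of the candidate and a fold of at least `E` over the
depth-scaled control expectation.

Two implementation choices matter here and are this package's own:

* **The counting flank scales with fragment size**:
  `flank = max(20, d/2)`. With 500–1000 bp fragments the sequenced tag
  ends sit 250–500 bp *away* from the site on both sides, leaving a
  central hole; a fixed ±20 bp window would contain no tags at any true
  site and the caller could never fire. Scaling the candidate region
  with fragment length is exactly how strand-based callers behave in
  practice.
* **The local control rate is estimated over ±max(flank, 2.5 kb)** and
  rescaled to the flank width. A raw control count inside the flank
  window alone, multiplied by a large depth ratio, would veto true
  sites whenever two background control tags happened to fall nearby;
  widening the estimation window gives the sparse control statistical
  support without changing its meaning.

Candidates closer than 20 bp merge keeping the higher-count one;
residual overlaps of the ±flank intervals are resolved preferring the
candidate with the stronger *bidirectional* support (larger minimum of
its forward and reverse counts, then larger total), since a true site
has tags on both sides while spurious transitions inside a one-sided
tag flank do not. The peak is `[t − flank, t + flank)` with the
transition as summit and the control fold as score.

## Coverage-threshold caller

A deterministic surrogate for calling peaks by eye: tags are extended
to the fragment length `d` from their 5' end, and maximal runs of at
least `m = 50` consecutive bases with coverage ≥ `E ×` genome-mean
coverage become peaks, provided the depth-scaled treatment/control
coverage ratio over the run also reaches `E` (sparse control coverage
is floored at the control genome mean so the ratio is always defined).
The score is the run's mean coverage in genome-mean units. This caller
is an explicit surrogate for a manual procedure that was never
quantified; it is not a reconstruction of it.

# Consensus

Cross-caller identity is defined by single-linkage clustering under
≥ 1 bp overlap with transitive closure: a chain of pairwise-overlapping
peaks is one cluster. The cluster interval is the union span — the
conservative choice for downstream overlap queries, which treat peaks
as regions of occupancy. Tiers are nested by construction
(`select(3) ⊆ select(2) ⊆ select(1)` in base coverage, a tested
invariant), Venn regions are counted per cluster (whether the original
study counted per peak or per merged cluster is not stated; per-cluster
is the deterministic choice), and caller order cannot change cluster
intervals.

# Annotation

Each peak receives exactly one category, tested in fixed precedence:
intragenic (gene body) ≻ promoter (5 kb upstream of the TSS, strand
aware) ≻ 5 kb downstream ≻ within 100 kb of the 5' end ≻ within 100 kb
of the 3' end ≻ gene desert. Precedence is required because the
categories are reported as exclusive percentages summing to 1; gene
body first mirrors the order in which such schemes are conventionally
listed. The 100 kb flanks are measured from the gene ends (so a peak
121 kb past a gene end is a desert), and a peak qualifying in several
genes is assigned the one with the nearest TSS (ties toward the smaller
coordinate). TSS distances use the peak midpoint — the summit would be
caller-dependent and an edge convention would be asymmetric — signed
negative upstream in the gene's orientation. Reflecting all coordinates
and flipping strands leaves every label unchanged (a tested symmetry).

# Coincidence

Overlap fractions are peak-level in both directions: a peak overlapping
two track intervals counts once, so the statistic matches "% of peaks"
and is invariant to splitting track intervals (tested). The track's
base coverage divided by genome length gives the expectation against
which over/under-representation is reported; between-condition
comparison is purely descriptive (fold change and difference, with a
guarded division when the denominator fraction is zero), because the
underlying analysis applies no significance test across conditions.

# Motifs

Windows are scored with `log2` odds of pseudocount-adjusted column
probabilities (`pseudocount = 1e-4`, probabilities renormalised) over
the background, which defaults to uniform unless the MEME file supplies
one. P-values are exact under the background model: column scores are
discretised to a 1/1000-bit grid and convolved by dynamic programming
into the full null distribution of the discretised score; an observed
score is rounded to the same grid before lookup, so the DP agrees with
brute-force enumeration of all 4^w words to ≤ 1e-9 (tested for widths
4–8 across dozens of random matrices). Scores below the achievable
minimum return p = 1; above the maximum they return the mass of the top
grid cell, the smallest value the discretisation can resolve. Cells
that are impossible under a zero pseudocount are floored 100 bits below
the finite minimum so they can never cross a threshold. Both strands
are scanned via the reverse-complemented matrix, intervals stay in
forward coordinates, and windows containing non-ACGT letters are
skipped.

Enrichment counts occurrences at the level of scannable window start
positions on both strands: `N = 2 Σ (L − w + 1)` for the genome,
`n` the same restricted to (disjoint) peak intervals, `K` and `k` the
positions scoring below the occurrence cutoff (default 1e-4).
Position-level units make the hypergeometric well defined and finite;
overlapping occurrences of one motif deliberately count separately, for
determinism and unit consistency. BH adjustment runs across all motifs
tested, significant at q < 0.05.

# Enrichment statistics

The hypergeometric upper tail is summed in log space (stable at genome
scale); `stats::phyper` and direct `dhyper` summation serve as
independent cross-checks in the tests, not as the implementation, so
the two routes stay distinct. BH is implemented as the explicit step-up
`q_(i) = min_{j≥i} p_(j) m / j`, cross-checked against `p.adjust`. One
property deserves a note: BH adjustment is *not* idempotent — feeding
q-values back through the procedure multiplies by `m/rank` again and
can change decisions near the threshold — so the package's tested
guarantee is the meaningful one: thresholding q at α reproduces the
step-up rejection set exactly. Terms with no selected gene are not
tested (they cannot be enriched, and excluding them reduces the number
of tests), and the universe defaults to all genes in the annotation
table. Ward clustering of binary profiles uses the Jaccard distance
(two all-zero profiles are at distance 0) with the Lance–Williams Ward
update applied directly to those distances — acknowledging the input is
not Euclidean, which is the standard pragmatic reading of "a distance
measure for binary attributes with Ward's method" — and a deterministic
lexicographic tie-break on the smallest original leaf indices.

# The simulator

`simulateDataset()` generates what the pipeline assumes and nothing
more: an i.i.d. genome at GC 0.41; non-overlapping 2–20 kb genes with
random strands; planted point sites at least 3 kb apart; per site a
Poisson number of fragments (mean `tagsPerSite`) with lengths uniform
on 500–1000 bp (the sonication range; a `"short"` preset at 140–160 bp
gives the conventional easy case for strand-shift methods), centres
jittered N(0, 50 bp), one end sequenced as a 36-base tag with a fair
coin choosing the strand — which produces the forward-upstream /
reverse-downstream asymmetry the strand caller exploits; uniform
background tags at 0.5/kb in both samples, with copy-number segments
multiplying background density in both; a CpG track built from islands
at about a third of TSSs plus random islands until coverage just
exceeds 1.5% of the genome; mark tracks covering site neighbourhoods
with configurable probabilities plus random background intervals; and
planted motif consensus instances within ±50 bp of a configurable
fraction of sites. Every operation seeds its own stream from the config
seed, so one config maps to one byte-identical output set (tested).

What it does **not** emulate — sequencing errors, PCR duplicates,
mappability, chromatin-state-dependent background, isoform structure —
bounds what green tests mean: they demonstrate correctness of the
algorithms under the stated statistical model, not performance on real
libraries, where duplicate filtering and mappability masking would have
to precede this pipeline.

The default ("strong") study conditions are 3 chromosomes × 300 kb,
60 sites × 60 tags mean, background 0.5 tags/kb — chosen once as a
desk-scale setting with the signal-to-noise of a good library, where a
correct caller should essentially saturate recall and precision. Under
these conditions all three callers and the ≥2-of-3 consensus recover
planted sites with recall and precision ≥ 0.9 (typically ≥ 0.98), a
planted motif is flagged at q < 0.05 with a decoy left unflagged, and
200 null replicates of the gene-set enrichment keep the empirical
false-positive rate within its nominal bound. Oracle suites run on
deliberately small instances: per-base brute force on ≤ 10 kb
chromosomes (100 random instances), exact hypergeometric summation at
N ≤ 10^4, full 4^w enumeration at w ≤ 8, and naive O(n³) agglomeration
at n = 8.

# Degenerate inputs and edge conventions

Empty treatment → empty peak set; empty control is an error for the
Poisson caller (its background is undefined) but not for the others;
single-strand input errors the shift estimator, yields zero peaks for
the strand caller. An empty gene table annotates everything as gene
desert with a warning; an empty track yields zero fractions with a
warning; an empty peak set is an error wherever a fraction over peaks
would be 0/0. Chromosome-length correlation is NA below three
chromosomes or at zero variance. Windows clipped away at chromosome
starts collapse to width zero and match nothing.

# Known limitations

The callers are simplified stand-ins, not reimplementations, of the
model-based, strand-based and manual methods they echo; no duplicate
filtering or paired-end support; no broad-domain calling; gene-desert
classification depends entirely on the completeness of the supplied
gene table; motif enrichment uses a 0-order background (no dinucleotide
model); and the two-condition comparison is descriptive by design.
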