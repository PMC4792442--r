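---
title: "Methods: low-coverage genome survey analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-coverage genome survey analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesurvey)
```

`genomesurvey` re-implements, as reusable and tested components, the
computations of a whole-genome shotgun *survey*: the kind of low-coverage
(~30x short-read) project used to get a first look at a large, heterozygous,
repeat-rich genome such as that of the Mediterranean mussel. This vignette
explains the models behind each component, the conventions chosen where the
procedures are conventionally under-specified, and what the synthetic-data
validation does and does not demonstrate.

## The k-mer spectrum of a diploid genome

For reads sequenced to base depth $c$ with read length $R$, each position of
the genome is covered by about $c_k = c \, (R - k + 1)/R$ windows of length
$k$ (the *k-mer depth*). If every distinct k-mer of a haploid genome of size
$G$ were unique, the histogram of k-mer multiplicities would be approximately
Poisson with rate $c_k$, and the total number of counted k-mers $N_k$ would
satisfy

$$ G \approx N_k / c_k. $$

`estimate_genome_size()` implements exactly this quotient, taking the
observed coverage-peak multiplicity as $c_k$. K-mers below the error trough
(`find_error_trough()`) are excluded from $N_k$ by default: on real reads,
sequencing errors generate a mass of near-unique k-mers at low multiplicity
that would inflate the numerator; on error-free data the trough is 1 and the
exclusion is a no-op.

In a diploid genome with per-site heterozygosity $h$, a k-mer overlapping a
heterozygous site exists on only one haplotype and is therefore sequenced at
half the depth of a homozygous k-mer. The spectrum becomes bimodal: a
*coverage peak* at $c_k$ (homozygous k-mers) and a *heterozygous peak* at
$c_k/2$. Which observed peak is which cannot be decided from one histogram —
but the expected number of distinct heterozygous k-mers grows linearly with
$k$ (each variant site disrupts $k$ windows on each haplotype, about
$2kh G$ k-mers in total), while the homozygous count $\approx G(1 - kh)$
barely changes for $kh \ll 1$. Comparing spectra across several $k$ (we use
15, 17, 19, 21, all odd so that no k-mer is its own reverse complement)
therefore identifies the heterozygous peak as the one whose height varies.
`classify_peaks()` formalizes this as: the peak whose height coefficient of
variation across $k$ is smaller is the coverage peak. A warning is emitted
if the resulting multiplicity ratio leaves $[0.4, 0.6]$, since the
half-depth law pins it near $1/2$.

Numerical conventions in peak handling:

* The histogram is smoothed with a centered moving average of window 3
  before trough and peak detection. Besides damping sampling noise, this
  breaks the exact tie between bins $\lambda - 1$ and $\lambda$ of a
  Poisson profile with integer rate; with finite counts the winner can
  still land one bin to either side, which is why stochastic checks accept
  a ±1 bin displacement of a detected peak.
* A local maximum whose smoothed height is below 5% of the tallest
  candidate is discarded (`min_height_frac`); this keeps tail noise of a
  unimodal spectrum from masquerading as a second peak while leaving any
  realistic heterozygous peak (tens of percent of the coverage peak)
  untouched.
* The trough is the smallest multiplicity $\ge 2$ where the smoothed
  histogram stops falling; a histogram rising from multiplicity 1 has no
  error component and the trough is 1. A monotonically decreasing
  histogram has no genomic peak and is reported as such.
* Counting is exact — canonical (strand-merged) k-mers in a hash table of
  2-bit-encoded words — because survey-scale simulations (megabases) make
  probabilistic counting unnecessary and exactness makes the
  window-conservation invariant testable: the histogram mass always equals
  the number of N-free windows.

## The five read-filtering rules

Raw pairs are dropped when any rule fails, with the first failing rule
recorded: (a) more than 5% ambiguous bases; (b) a poly-A structure; (c) at
least 20 low-quality bases; (d) adapter contamination — at least 11 bases
aligned to the adapter with at most 3 mismatches, at any ungapped offset
including partial overhangs; (e) mate overlap — the reverse complement of
mate 2 aligns to mate 1 over at least 10 bp with at most 10% mismatches.
Two thresholds the published wording leaves open are fixed as configurable
conventions: "poly-A" means whole-read A-fraction at or above 0.80, and
"low quality" means Phred score at or below 7. Whole pairs (not single
mates) are dropped, which keeps mate files synchronized. No trimming is
performed: the procedure modelled here discards reads, it does not repair
them.

Two operating characteristics of these rules matter for validation design:

* **Rule (d) has an irreducible chance-hit rate.** An 11-base alignment
  tolerating 3 mismatches requires only 8 matching bases; on uniform random
  DNA the probability that a read end matches the adapter that well is
  about $1.6 \times 10^{-3}$ per end ($\sum_{j\ge 8}\binom{11}{j} 4^{-j}
  (3/4)^{11-j} \approx 1.1\times10^{-3}$ for the flush offset alone), i.e.
  roughly 6 in 1,000 pairs are dropped by chance. This is a property of
  the rule itself, not of any implementation. The planted-label tests
  therefore assert that the drop set equals the planted set *up to* such
  chance hits, and verify each surplus drop against an independent
  brute-force scanner rather than pretending the background is zero.
* **Rule (e) is tautological for 180-bp libraries.** With 100-bp reads, a
  180-bp fragment always overlaps its mates by 20 bp, so every clean pair
  of the short-insert library is — correctly — dropped. Planted-label
  recovery is therefore validated on 500/800-bp libraries, where genuine
  overlaps cannot occur; the `apply_overlap_filter_only_to_short_insert`
  switch exists for workflows that restrict rule (e) to the short library.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
analyses assume, plus ground-truth labels:

* **Diploid genomes** diverge by SNVs only. Keeping the haplotypes
  indel-free preserves a single coordinate system, so variant positions,
  heterozygous k-mer counts and planted SNVs are exact truths. This
  matches the scope of the analyses (neither indel heterozygosity nor
  structural variation is modelled downstream).
* **Reads** are drawn uniformly from both haplotypes in equal proportion,
  as 100-bp pairs from 180/500/800-bp fragments, with independent
  per-base substitution errors. Base qualities are Phred+33 at Q35 with a
  small per-read jitter. Violation classes are planted disjointly (one
  uniform draw per pair), each by rewriting the pair: an N-block covering
  10% of mate 1; an A-tail covering the final 85% of mate 1 (large enough
  that the whole-read A-fraction detector at 0.80 must fire — a 40% tail
  would leave the read below any defensible whole-read threshold); twenty
  Q2 bases; a 30-bp adapter suffix; or a redraw from a 150-bp fragment
  giving a 50-bp mate overlap.
* **Mitochondrial pairs** emulate the two mitochondrial genomes mussels
  carry under doubly uniparental inheritance: an M-type sequence derived
  from the F-type at a configurable divergence, sequenced at a
  copy-number-determined fraction (default study condition: about 10 times
  less) of the F depth, with Poisson read counts and reads drawn on the
  doubled sequence so they wrap the circular origin.
* **CEG match tables and GO count tables** are drawn with the exact class
  boundaries and binomial count model the downstream classifiers assume,
  with planted enrichment folds recorded.

What the generator deliberately does *not* model: quality-by-cycle decay,
GC bias, PCR duplicates, chimeric fragments, or indel errors. Passing tests
on these simulations therefore demonstrate the correctness of the decision
rules and estimators under their own assumptions — not robustness to every
artefact of real Illumina data.

## Assembly, contamination and mitochondrial analyses

**Assembly statistics** follow the Assemblathon-2 conventions: scaffolds
split into contigs at runs of at least 25 Ns (a *captured gap*); N50 is the
largest $L$ such that scaffolds of length $\ge L$ hold at least half the
assembly; the assembly partitions into scaffolds with ($\ge 2$ contigs) and
without captured gaps. Repeat landscapes are summarized from given masked
intervals (0-based half-open) as per-family and per-class interval unions —
overlap within a family is never double-counted.

**Contamination screening** is the two-stage rule applied before gene
prediction: a contig is a *candidate* when the union of its classifier
match spans strictly exceeds 10% of its length ("accumulated length" is
read as the merged union, the conservative interpretation), and *confirmed*
when its best protein hit — lowest e-value, ties broken by highest
bit-score, unresolvable ties treated as not confirmed — is bacterial at
e-value $\le 10^{-6}$. Only confirmed contigs are removed. The k-mer
classifier and the protein search themselves are consumed as tabular
inputs, not re-implemented: the contribution is the decision rule.

**Mitochondrial isolation** keeps contig alignments with e-value
$\le 10^{-6}$, identity $\ge 90\%$ and per-contig accumulated query
coverage $\ge 90\%$ (coverage is read as the per-contig union across
records, so a contig split over two alignment records still qualifies). The
tiling path is a greedy left-to-right chain — among unused records starting
within `max_gap` of the covered end, take the one extending furthest right;
records contained in the tiled span are skipped; holes are reported as gaps
— with records shorter than 100 bp ignored, honouring the spirit of the
`-c 100` minimum-cluster convention of whole-genome aligners. With
unlimited `max_gap` the tiled coverage provably equals the plain union
coverage.

**Read placement and variant calling** on the small circular genome use an
exact-seed (21-mer), ungapped-extension placer on the doubled reference,
with positions reported modulo the genome length and ambiguous best
placements left unmapped; SAM from a full aligner can be substituted. The
SNV caller states an explicit rule — depth $\ge 10$, leading non-reference
allele count $\ge 4$ and fraction $\ge 0.2$ — because the thresholds of the
historical callers used in survey papers are buried in tool versions; the
real-data variant counts of any particular study are reproducible only with
its original toolchain, while the rule's recall and precision are measured
here on planted variants ($\ge 0.95$ at 50x with 0.1% error). Overlapping
gene annotations attribute a variant to every covering gene.

## Completeness, extrapolation and GO comparison

A core eukaryotic gene is *complete* when a significant alignment spans
strictly more than 90% of the protein, *partial* when it is significant but
shorter. Percentages are recomputed from the counts and rounded half-up to
two decimals; published tables that disagree with their own counts (e.g. a
printed 43.27% where 107/248 = 43.15%) are *not* matched — the module
reports the arithmetic truth of its inputs. The repertoire extrapolation
divides the number of predicted genes by a completeness fraction;
conventionally the partial fraction, since in a fragmented low-coverage
assembly a truncated gene is still evidence of presence. Both the raw
quotient and its nearest-thousand rounding are reported.

The GO comparison tests each term's 2x2 count table with the two-sided
Fisher exact test (the usual "sum of no-more-likely tables" convention;
sidedness is configurable), adjusts across all tested terms with
Benjamini–Hochberg at FDR 0.05, and reports the conventional direction
symbols (`++` overrepresented, `--` underrepresented, `⌘` not significant).
Terms annotated in neither set are excluded from the multiple-testing
burden; no GO-graph propagation is performed — counts are compared as
given, as in level-sliced annotation comparisons.

## Validation scales

The test suite exercises the pipeline at sizes chosen to be statistically
informative for a desk-scale package: the headline spectrum check simulates
a 2-Mb diploid genome with 1% heterozygosity at 32x 17-mer coverage (about
64 million counted 17-mers) and expects the heterozygous and coverage peaks
at 16 and 32 (±1 bin, by the integer-rate tie noted above); genome-size
recovery and depth-rescaling invariance use 300-kb genomes at 30x and 60x;
the half-coverage ratio and height-stability classification use four k
values on a 300-kb, 1%-heterozygosity genome; SNV recall/precision pools
five 8-kb mitochondrial simulations at 50x; the null calibration of the
FDR procedure uses 500 simulated 40-term comparisons. These sizes are the
package's own choices of informative-yet-fast study conditions; all scale
linearly if larger runs are wanted.

## Known limitations

* The spectrum analysis is peak-based, as in the original procedure; no
  mixture model is fitted, so heterozygosity and repeat content are not
  estimated jointly and very low heterozygosity (het peak under 5% of the
  coverage peak) is classified as a single-peak spectrum.
* The read placer is exact-seeded and ungapped; it is intended for clean
  short reads on kilobase-scale circular references, not as a general
  aligner.
* Real-data headline numbers of any particular survey (total genome size,
  assembly tables, real variant counts, real enrichment lists) depend on
  the original reads, assemblies and tool versions; this package validates
  the *computations* on synthetic data with known truth.
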