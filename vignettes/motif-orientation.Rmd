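---
title: "Testing orientation and arrangement preferences of promoter motifs"
author: "motifOrient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing orientation and arrangement preferences of promoter motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifOrient)
```

## The question

A transcription-factor binding site read 5'→3' on the coding strand and
its reverse complement present the same double-helix interaction surface,
rotated by 180° relative to the transcription start site (TSS). Whether
that rotation matters for regulation is an empirical question: if it
does, a motif should map to gene upstream regions more often in one
orientation than composition alone predicts, and the genes carrying the
favored orientation should be more strongly co-expressed. motifOrient
implements the complete statistical machinery for asking this question —
motif catalog curation, orientation-resolved scanning, composition-
corrected orientation tests, positional entropy, dinucleotide asymmetry
profiles, co-expression comparisons, randomized-motif controls and
motif-pair arrangement statistics — together with a synthetic-promoter
generator that provides ground truth for validating every stage.

## Inputs and conventions

Three inputs drive an analysis:

* a motif catalog (IUPAC consensus strings with source tags),
* coding-strand upstream sequences of fixed length (default 500 nt),
  one per gene, with the 3'-terminal base at upstream position −1
  immediately 5' of the TSS,
* a normalized, log-scale expression matrix (genes × samples).

Upstream coordinates are 1-based-negative closed intervals; the interval
(−100, −1) is the 100 nt immediately upstream of the TSS. Interval scans
operate on the excised subsequence, so a match can never straddle an
interval boundary, and a hit belongs to the interval containing its
5'-most base — a single unambiguous anchor that also drives positional
binning.

Scanning follows global string-matching semantics: all leftmost-greedy,
mutually non-overlapping matches of the (possibly ambiguous) consensus,
with the forward and reverse-complement scans run independently against
the same coding strand. Ambiguity codes in the *scanned sequence* never
match: a genomic `N` (masked or uncertain base) is not evidence of a
binding site, and counting it would inflate hit numbers on low-quality
sequence. Ambiguity codes in the *motif* expand to their allowed base
set.

## Catalog curation

`curate_catalog()` applies, in order: trimming of terminal `N`s; removal
of motifs with fewer than four unambiguous bases (too unspecific to
map); removal of motifs with a run of four or more consecutive `N`
(read as a run because isolated `N`s are common and innocuous in
PBM-derived consensus strings, while an `NNNN` wildcard would swallow
every shorter motif in containment checks); removal of exact duplicate
strings; flagging of palindromic motifs, which are excluded from all
orientation analyses because their two orientations are the same string;
and flagging of contained motifs. Containment is checked both on the
literal strings and, optionally, per position on the variant sets (a
motif is contained when each of its positions allows a subset of the
bases allowed by the aligned position of a longer motif, at any offset).
Contained motifs stay in single-motif analyses but are excluded from
pair analyses, where a contained motif would co-occur with its container
by construction. Containment is evaluated in the forward orientation by
default; a `rc_containment` switch also tests against reverse-
complemented longer motifs for users who consider a motif redundant with
its container's other strand.

## Orientation statistics

Under a zero-order background, the probability that a mapped instance of
motif $m$ is a forward rather than reverse-complement match is

$$F_m = \frac{P_{fw,m}}{P_{fw,m} + P_{rc,m}}, \qquad
  P_{fw/rc,m} = \prod_i \sum_{b \in \text{allowed}_i} p_b,$$

with $p_b$ the base frequencies of the analyzed interval (ambiguity
positions sum their allowed bases; fractional counting handles ambiguous
genomic positions in the composition itself). This correction matters
because promoter-proximal sequence is compositionally asymmetric — C is
systematically more frequent than G near the TSS (CG skew) — so even a
random motif maps asymmetrically. A palindromic consensus always has
$F = 0.5$.

Observed forward counts among $n_{fw} + n_{rc}$ mappings are tested
against $F_m$ with an exact binomial test. The two-sided p-value uses
the minimum-likelihood convention (sum of all outcome probabilities not
exceeding that of the observed count), the convention of
`stats::binom.test`; the preferred orientation is the sign of
$\log\left[(n_{fw}/n_{rc}) \big/ (F_m/(1-F_m))\right]$. Motifs with
fewer than 10 mappings in an interval are not assessable and are
excluded from the multiple-testing family. Benjamini–Hochberg correction
is applied per analysis type and interval; the filter cascade applies
its thresholds to the adjusted values by default (a `use_adjusted`
switch exposes raw p-values).

### Positional entropy

Positional preference is quantified as the Shannon entropy of the hit
distribution over 10 equal bins of the full-length region,
$PE = -\sum_i p_i \ln p_i$ (natural log, $0 \ln 0 = 0$), computed per
orientation from hit start positions. Uniformly spread hits give
$\ln 10 \approx 2.30$; hits confined to one 50-nt bin give 0. The sign
convention is chosen so that PE is a proper (non-negative) entropy whose
maximum is attained by positional indifference; confinement lowers it.
Entropy is only computed for full-length scans — within a short
interval, positional preference loses its meaning.

### Co-expression comparisons

A motif's regulatory relevance is probed by comparing distributions of
pairwise Pearson correlation coefficients between gene sets. The
presence/absence comparison contrasts genes carrying the motif (either
orientation) with a seeded random sample of motif-free genes sized
`max(|positive|, 100)` — capping what would otherwise be tens of
thousands of negatives while guaranteeing a floor for rare motifs. The
orientation comparison contrasts genes carrying the motif in the forward
orientation *only* with genes carrying it in the reverse-complement
orientation *only*; genes with hits in both orientations are excluded
from both sets. Differences are tested with a two-sided Wilcoxon
rank-sum test and sized with Cohen's d, the difference of means over the
square root of the average variance. Correlation pairs sharing a gene
are not independent; treating them as such faithfully reproduces the
established co-expression protocol and is adequate for ranking and
calibration against randomized controls, but the p-values should not be
read as exact — a caveat that applies equally to the protocol this
package reimplements.

All-pairs computation is capped at 500,000 pairs per set; beyond the cap
a seeded uniform subsample of pairs is used, keeping desk-scale runs
deterministic and fast while changing set means by far less than their
sampling error.

### The filter cascade

Per interval, motifs pass through nested filters: **C** — significant
presence/absence co-expression difference (p < 0.05 and Cohen's
d > 0.01); **D1** — significant orientation preference; **D2** — D1 plus
a significant orientation-set co-expression difference with the higher
correlations in the preferred orientation's gene set; **D3** — D2 plus
strictly lower positional entropy in the preferred orientation (500-nt
scans only); **E** — the D2 condition evaluated within the C-positive
subset, with the BH families re-formed over that subset (correcting over
a restricted family is what makes E a distinct, properly-corrected
filter rather than an intersection); **F** — E plus the entropy
condition. Motifs missing any component statistic (too few mappings, no
measurable genes, an orientation set below two genes) are reported as
incomplete and excluded from the cascade counts.

## Dinucleotide orientation asymmetry

Zero-order composition cannot explain orientation preference once $F_m$
corrects for it, so the next suspect is first-order structure. For each
of the 16 dinucleotides the occurrence ratio
$R_{B_1B_2} = f_{B_1B_2} / (p_{B_1} p_{B_2})$ compares the observed
frequency (overlapping counts, within windows, never across gene
boundaries; ambiguous positions skipped) with the expectation under
positional independence, and the dinucleotide orientation ratio
$DOR = R_{B_1B_2} / R_{rc(B_1B_2)}$ compares a dinucleotide with its
reverse complement. $DOR \ne 1$ means the forward succession of two
bases is preferred over its reverse-complement succession — intrinsic
sequence directionality that makes even composition-corrected random
motifs map asymmetrically. Palindromic dinucleotides (AT, TA, CG, GC)
have $DOR = 1$ identically, and $DOR(d) \cdot DOR(rc(d)) = 1$ for all
pairs, so log2 profiles are antisymmetric. Counts are pooled across
genes before normalization (the simplest reading; per-gene normalization
would re-weight genes by their informative length).

## Randomized-motif controls

Observed pass rates only mean something relative to what random motifs
achieve. `generate_random_motifs()` replaces every true motif by
`multiplier` random motifs of identical length (default 5), drawn i.i.d.
per position from either the analyzed interval's base composition (R1 —
canonical bases only) or the character frequencies of the true motifs
including ambiguity codes treated as atomic characters (R2). Random
catalogs pass through the same curation as true motifs, and
`run_control_battery()` compares per-filter pass rates with two-sided
Fisher exact tests, BH-corrected. The interval-resolved orientation
profile averages random pass rates over 10 freshly generated catalogs.

## Motif pairs

Pair analyses use only the truly uncontained motif subset and, by
default, the interval (−500, −51) that excludes the core promoter. A
pair instance is one non-overlapping combination of one hit of each
motif in the same gene; a gene contributes all its valid instances to
arrangement counts but only once to gene-level co-occurrence counts
(arrangements are events, co-occurrence is a gene property).
Co-occurrence enrichment is the upper-tail hypergeometric probability
in a universe defaulting to all genes with an upstream sequence
(configurable to the expression-measurable subset).

For distinct motifs each instance falls in one of 8 cells (2 orders ×
4 orientation combinations); same-motif pairs have 4 cells (orientation
of the upstream and downstream hit; order is meaningless). Arrangement
preference is tested with the entropy of the cell frequencies after
adding a pseudocount of 1 to every cell, against an empirical null of
`n_shuffles` (default 100,000) multinomial-uniform draws of the same
total; the empirical p is the fraction of null entropies strictly below
the observed one (reported as 0 with a stated floor of `1/n_shuffles`
when no draw is smaller; an `(r+1)/(B+1)` variant is available). Motif
order alone is tested with an exact binomial at 50%, and 4-cell entropy
tests within each order separate genuine orientation-arrangement
preference from mere order imbalance: a pair is arrangement-preferring
only when the 8-cell test and both order-conditional tests are
significant after BH. Pairs need more than 5 co-occurring genes to be
reported and at least 50 instances for arrangement tests. The "most
frequent arrangement" used in arrangement-level co-expression breaks
ties by the lexicographically first cell label.

## The synthetic world generator

`synth_world()` builds complete ground-truth worlds:

* **Sequence** — each region is generated 5'→3', window by window, from
  first-order Markov models (first-order because dinucleotide-level
  directionality is exactly the structure the DOR analysis measures; a
  window's first base after the first window is conditioned on the
  previous window's last base). Uniform i.i.d. models give null worlds;
  a biased transition such as $P(C\,|\,T) = 0.30$ in the proximal window
  implants a known, window-localized log2 DOR(TC) > 0.
* **Implants** — each configured motif is written over the background
  (region length preserved, so TSS-anchored coordinates stay intact) in
  a uniformly chosen concrete variant, with configurable per-gene
  probability, forward-orientation probability and positional bin
  distribution; sites never overlap previous implants, and every
  implant is recorded in a truth table.
* **Expression** — genes sharing an implanted motif load on a common
  standard-normal latent factor, $x_{gs} = \sum_f \lambda_f z_{fs} +
  \varepsilon_{gs}$; with loading $\lambda$ and unit noise the expected
  within-module correlation is $\lambda^2/(\lambda^2+1)$, an exact
  closed form the tests verify.

Two presets define the reference conditions. The *null world* (uniform
sequence, a catalog of never-implanted random 7-mers whose hits arise by
chance alone, pure-noise expression) is the false-positive calibration
condition. The *oriented world* implants one motif at an 80:20
forward:reverse ratio — forward instances confined to the three
TSS-proximal bins and sharing a $\lambda = 0.5$ co-expression module,
reverse instances uniform and module-free, making orientation
functionally distinguishable — plus an unbiased, uniformly placed
second motif and the proximal T→C transition bias. Preset defaults are
2,000 genes × 500 nt × 200 samples; the test suite runs reduced worlds
(250–800 genes, 40–120 samples) chosen to keep the full suite in the
low minutes while leaving every effect far above its detection
threshold, and the calibration battery uses 100 null worlds of 250
genes with 15 motifs each.

What the generator does *not* emulate: repeats and low-complexity
sequence, nucleosome positioning signals, array-specific noise,
correlated experimental conditions, or TSS annotation error. Passing on
synthetic worlds therefore demonstrates correctness of the statistical
machinery under its own model assumptions, not robustness to every
artifact of real genomic data.

## Numerical choices

* Two-sided binomial p-values use the minimum-likelihood convention;
  the doubled-smaller-tail alternative differs only in asymmetric cases
  and is not exposed.
* Greedy leftmost matching (not maximum-cardinality packing) is pinned
  because the two coincide for fixed-length patterns and greedy
  semantics are testable against a simple oracle.
* The `max(|positive|, 100)` negative-set draw and the pair subsample
  are seeded per motif; all pipeline functions take explicit seeds and
  never touch the caller's RNG state.
* Degenerate inputs fail loudly: empty curation results, intervals
  exceeding the region, compositions with missing bases, sets below two
  measurable genes (marked not-assessable rather than guessed).
* `DOR` is `NA` (flagged) when the reverse-complement ratio is zero;
  palindromic dinucleotides are reported as exactly 1 rather than
  recomputed as a ratio of identical quantities.

## Limitations

Wilcoxon tests on overlapping correlation pairs are anti-conservative
in principle (see above); the randomized-motif controls, which inherit
the same dependence, are the appropriate yardstick. The arrangement
null assumes instances are exchangeable across cells, ignoring that one
gene can contribute several instances. PWM or HMM motif models,
mismatch-tolerant scanning and higher-order (k > 2) asymmetry are out
of scope.
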