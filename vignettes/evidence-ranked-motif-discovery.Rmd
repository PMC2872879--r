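---
title: "Evidence-ranked discovery of degenerate sequence motifs"
author: "evimotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-ranked discovery of degenerate sequence motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evimotif)
```

## The problem and the model

Classic motif finders ask: given a hand-picked set of co-regulated
sequences, which short pattern is over-represented?  Modern genome-wide
assays (ChIP-chip, ChIP-seq, factor over-expression followed by expression
profiling) instead deliver *quantitative evidence of regulation for every
region in the genome*, and thresholding that evidence to define a "bound
set" throws information away and forces an arbitrary cutoff.

`evimotif` works on the un-thresholded data.  The input is a sequence space
of $d$ putative regulatory regions $S = \{s_1, \dots, s_d\}$ with a
per-region evidence vector $E = \{e_1, \dots, e_d\}$.  Any candidate motif
$m$ — a fixed-length word over the 11-symbol degenerate IUPAC alphabet
$\{A,C,G,T,W,K,R,Y,S,M,N\}$ — partitions $S$ into the *positive set* (the
regions containing at least one exact match to $m$, on either strand for
DNA, forward-only for RNA) and its complement.  The quality of the
partition is scored by a gene-set-enrichment-style statistic: the centred
and scaled average evidence of the positive set relative to a random set of
the same size,

$$ J(m) \;=\; \sqrt{n}\;\frac{\bar e^{+} - \bar e}{\sigma_E}, $$

where $n$ is the positive-set size, $\bar e^{+}$ its mean evidence, and
$\bar e$, $\sigma_E$ the mean and population standard deviation of the full
evidence vector.  $J$ is invariant to positive affine rescaling of $E$, so
the choice of logarithm base in the evidence transforms affects reported
magnitudes but never rankings.  An optional finite-population correction
multiplies the denominator by $\sqrt{(d-n)/(d-1)}$ (the exact variance of a
mean drawn without replacement); the plain form is the default.  A
thresholding variant `selection_score()` first binarises the evidence at a
user threshold $k$ — it is provided for comparison, but averaging is the
default because it needs no extra parameter and is less noise-sensitive.

Very small and very large positive sets give high-variance, unstable
scores, so admissible motifs are constrained to
$a \le n \le \lfloor b \cdot d \rfloor$ (both bounds inclusive).  Two named
presets reflect the two data scales: `chip-chip` ($a = 20$, $b = 0.15$, also
used for over-expression data) and `chip-seq` ($a = 100$, $b = 0.30$).
These bounds are effectively the only user-set parameters of the search.

## Evidence transforms

All transforms express a per-region log-odds of regulation:

* **ChIP-chip P-values.**  Treating a P-value as an odds ratio (the
  "P-value fallacy") overstates the evidence: $p = 0.001$ does not mean
  1000:1 odds of binding.  `pvalue_evidence()` uses the calibration upper
  bound on the Bayes factor of binding versus non-binding under a
  Beta$(\theta, 1)$ family of alternatives,
  $B_{10}(p) \le 1 / (-e\,p\log p)$ for $p < 1/e$, and takes
  $e_j = \log B_{10}(p_j)$.  At $p = 0.001$ the denominator is $0.0188$,
  i.e. odds of about 50:1.  For $p \ge 1/e$ the bound is clamped to 1
  (zero evidence) because the formula is only meaningful below $1/e$ and
  null-consistent P-values should never yield negative evidence.  A
  `neglog` switch substitutes the naive $-\log p$ for comparison.
* **ChIP-seq peak densities.**  Each region contributes the maximum of a
  kernel-density read score over its positions; `chipseq_evidence()`
  returns $e_j = \log(s_j / b)$ where the background $b$ is the 85th
  percentile (linear interpolation between order statistics — the least
  surprising percentile definition) of the strictly positive scores.
  Zero-score regions are floored at $10^{-3}$ times the smallest positive
  score so their evidence stays finite.
* **Expression fold-changes.**  For repressor (e.g. miRNA over-expression)
  studies, $e_j = -\log_2(x_\mathrm{after}/x_\mathrm{before})$, so
  down-regulation upon induction is positive evidence; a flag flips the
  sign for activator studies.

## The search

Every non-degenerate 5-mer seeds one greedy trajectory; in DNA mode a word
and its reverse complement describe the same double-stranded pattern, so
the $4^5$ words pool to 512 canonical seeds (RNA mode keeps all 1024 and
matches forward-only).  At each step the current motif's neighbourhood is

* **extension**: prepend or append each base (8 candidates, up to length 20),
* **truncation**: drop either flank (2 candidates, from length 6),
* **degeneracy**: widen one position (a base to each of the three
  double-degenerate codes containing it; a double-degenerate code to `N`,
  never at the flanks; `N` is terminal) — $3k$ candidates for a clean
  $k$-mer, $k-2$ for a fully double-degenerate one.

Admissible candidates are scored and the best is adopted only on strict
improvement, with exact ties broken by the lexicographically smallest motif
string, so the whole search is deterministic.  Occurrence queries go
through a suffix array over the concatenated regions with
branching binary-search descent over degenerate symbols; degenerate motifs
are never expanded into literal word lists, and sentinel separators keep
matches from spanning regions.  A sequence `N` (masked or ambiguous base)
is matched only by motif symbol `N`, so masked stretches cannot fabricate
positive-set members.

One design point deserves emphasis.  In realistic region sets a
non-degenerate 5-mer occurs in far more than $b \cdot d$ regions — in 200-nt
regions a given 5-mer is present in roughly a third of them — so seeds
typically start *outside* the admissible window.  Such seeds carry score
$-\infty$: the climb still proceeds, and the first admissible candidate
(usually an extension, which shrinks the positive set) enters the window;
inadmissible candidates are never adopted at any later step, and a
trajectory that never reaches an admissible motif is dropped as invalid.
Recovery of longer sites whose 6-mer subwords are still over-populous
happens through degenerate-flank intermediates (e.g. `WTGACTC` →
`WTGACTCA` → truncate → `TGACTCA`), which is exactly the behaviour the move
set is designed to allow.

When ortholog sequences are supplied, conservation refines each positive
set: a region stays only if the motif also occurs in *every* available
ortholog of that region; regions without orthologs stay unconditionally,
so partial ortholog coverage never shrinks the usable dataset.

## Post-processing

The evolved motifs are ranked by score, de-duplicated (a motif and its
reverse complement merge onto the canonical form), and summarised:

* **PSSM**: every match window in the positive set contributes one aligned
  word (reverse-strand windows are reverse-complemented into motif
  orientation); columns are empirical base frequencies.  The pseudocount
  defaults to 0 — pure empirical counts — and is configurable for
  downstream use.  Windows containing `N` are skipped.
* **Similarity**: for equal widths the column distance is
  $D(a,b) = \frac1w \sum_i \sqrt{\frac12 \sum_L (a_{iL}-b_{iL})^2}$; the
  similarity of two PSSMs is $1 - D$ maximised over all overlap shifts and
  (for DNA) both orientations, with minimum overlap 6 columns, relaxed to 5
  when either motif is 5 wide.  Distances are computed on the overlapping
  columns only, normalised by overlap width.
* **Redundancy**: two predictions are merged when similarity $\ge 0.75$
  *and* they co-occur in the same regions (nearest occurrences within
  $\tau$ nucleotides; default $\tau = 50$, a scale chosen to capture
  same-enhancer co-occurrence) more often than the hypergeometric chance
  expectation (upper-tail $P \le 0.05$).  Clustering peels the ranked
  list greedily: the best remaining motif becomes a representative and
  absorbs everything similar to it, so clusters partition the list and
  earlier clusters have higher scores.  Membership is evaluated against
  the representative only, not transitively.
* **Cluster PSSM**: members are aligned into the representative's frame via
  their best similarity alignment and averaged column-wise, weighted by
  motif score (negative weights floored at 0), then renormalised.

## Significance

The top score of a search has no analytic null, so `permutation_null()`
shuffles the evidence across regions (sequences untouched), reruns the full
search, and records the maximum score, $\Pi = 100$ times by default.  A
Gamma distribution fitted by maximum likelihood summarises the permutation
maxima; the P-value of an observed score is the fitted upper tail.  The
parametric tail is the point: at working thresholds like $10^{-4}$ an
empirical histogram would need millions of permutations, while the Gamma
extrapolates from a hundred.  The shape equation is solved by Newton
iteration so the MLE moment identity (shape $\times$ scale $=$ sample mean)
holds to machine precision; scores that are not strictly positive (possible
in degenerate cases) are shifted by their minimum minus a small epsilon
before fitting, and the offset is stored with the fit.  Because positive
sets do not depend on the evidence, motif-to-positive-set lookups are
cached across permutations; with `evolve = FALSE` (exhaustive fixed-length
scoring, useful for calibration studies) the whole seed family is scored
through one sparse indicator matrix.

## ChIP-seq preprocessing

For deep-sequencing inputs the package consumes aligned reads and
kernel-density peak scores (peak calling itself is upstream):
`filter_alignments()` keeps reads with at most four genomic hits, removes
single-base pile-ups (a 30-bp window holding more than 10 reads with at
least 70% on one base loses that base), and trims per-location tag counts
to five — in that order.  `normalize_peaks()` discards extreme-score peaks
(default cutoff: the 99.9th score percentile, standing in for a list of
known over-represented regions such as mitochondrial or ribosomal DNA; the
cutoff is configurable and should be set explicitly when a calibrated
threshold exists) and clamps peak widths to [100, 1000] bp, resizing each
flank proportionally to its distance from the summit.
`define_regions_ensemble()` pools the top 5000 peaks per factor and merges
overlaps — an open-chromatin surrogate for organisms without accessibility
data — and `assign_evidence()` gives each region the maximum score of the
overlapping factor peaks (any overlap counts; regions without overlap score
0 and end up at the evidence floor).

## The synthetic generator, and what passing tests mean

`synthesize_dataset()` emulates the core statistical structure the method
assumes: a planted motif induces a partition with elevated evidence.  It
draws iid uniform-composition regions, inserts one exact instantiation of
the planted IUPAC motif at a uniform position in a fixed fraction of them,
and sets evidence to $\Delta \cdot \mathbb 1(\text{planted}) + N(0,
\sigma^2)$.  The defaults — 500 regions of 200 nt, the AP-1 heptamer
`TGACTCA` planted in 10% of regions, $\Delta = 3$, $\sigma = 1$ — describe a
clearly detectable but non-trivial signal (planted set of 50 against a
background of incidental matches).  Real data differ in ways the generator
deliberately ignores: non-uniform base composition, repeats and masking,
multiple motif copies with position preference, correlated evidence noise,
and evidence effects that scale with occurrence count.  Passing the
recovery tests therefore demonstrates the machinery is correct under the
model's own assumptions, not that any particular biological dataset will
yield its motif.

## Numerical choices and reproducibility

* Ties in the hill climb break lexicographically; result lists sort by
  score, then motif string — searches are bit-reproducible.
* The upper size bound uses `floor` and both bounds are inclusive.
* Percentiles use linear interpolation (R's default type 7).
* Reported percentage rates round half away from zero.
* PSSM columns are validated to sum to 1 within $10^{-9}$.
* All randomness (fixtures, permutations) flows through explicit seeds.

The statistical studies in the test suite run at deliberately moderate
problem sizes: the planted-motif recovery uses the generator defaults above
(full 512-seed search, clustered); the significance-calibration study uses
one fixed set of 200 random 200-nt regions, an exhaustive 6-mer search, 200
replicates of pure-noise evidence and 100 permutations each, testing the
resulting P-values against uniformity by a Kolmogorov–Smirnov test.

## A worked example

```{r example}
sim <- synthesize_dataset(d = 300, region_length = 150,
                          motif = "TGACTCA", planted_fraction = 0.12,
                          effect = 3, noise_sd = 1, seed = 7)
fit <- evimotif(sim$regions, sim$evidence, a = 15, top_m = 10)
fit
summary(fit)$clusters[1, c("representative", "score", "consensus")]
```

## Known limitations

* IUPAC consensi can under-represent true degeneracy; the PSSMs are built
  post hoc from consensus occurrences and should be read as the core of a
  functional element, not a quantitative binding-affinity model.
* Gapped/spaced motifs, two-block dimer sites and stochastic search moves
  are out of scope.
* The greedy climb is locally optimal per seed; the 512-seed ensemble, not
  any single trajectory, is what makes recovery reliable.
* Binding is modelled as a binary presence event, which presumes the
  assayed factor is not concentration-limited.
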