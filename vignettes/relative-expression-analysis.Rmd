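---
title: "Relative expression analysis: methods and design"
author: "relexp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative expression analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relexp)
```

## The problem and the modelling idea

Two-class phenotype comparisons of transcriptomic data (tumour versus
normal tissue, responder versus non-responder, and so on) are usually
attacked with classifiers built on absolute expression levels, which
makes them sensitive to normalisation, platform and batch. Relative
expression analysis instead builds classifiers from *within-sample
orderings*: the basic observable is the relative expression reversal,
the event that gene *i* is expressed above gene *j* in one phenotype
and below it in the other. Because each sample is only compared with
itself, every statistic in this package is invariant under any
strictly monotone per-sample transformation of the data — quantile
normalisation, log transforms and scale differences between platforms
simply do not matter. The price is a loss of magnitude information;
the gain is robustness and directly interpretable signatures ("gene A
overtakes gene B in disease").

`relexp` implements four classifiers on this principle behind one
train/classify/cross-validate contract:

* **TSP** — the single best-reversing gene pair.
* **k-TSP** — an odd-sized set of gene-disjoint top pairs combined by
  majority vote, with the set size picked by internal cross-validation.
* **TST** — the gene triple whose distribution over the six
  within-sample orderings differs most between classes.
* **DIRAC** — predefined gene sets ("networks", e.g. pathways) scored
  by how well class-specific rank templates separate the classes.

## Scores and estimators

**Ranks.** Within each sample, genes are ranked with rank 1 for the
lowest value and average ranks for ties — the standard rank-statistics
convention, chosen because it is deterministic and keeps rank sums at
$n(n+1)/2$. Whether the original implementations of these methods
broke expression ties this way is not documented anywhere we know of;
average ranks are this package's explicit choice.

**TSP.** For a pair $(i, j)$ and class $c$, the ordering probability
$p_c = P(X_i < X_j \mid c)$ is estimated by the empirical per-sample
frequency, a tied sample contributing $1/2$. The pair score is
$\Delta = |p_1 - p_2| \in [0, 1]$. Training maximises $\Delta$
exhaustively over all pairs. Ties on $\Delta$ are broken by the
secondary score $\gamma$, the absolute between-class gap in the mean
within-sample rank difference of the two genes (the convention of the
k-TSP literature), and remaining ties lexicographically by gene
position, so training is fully deterministic.

**TST.** A triple of genes induces one of $3! = 6$ orderings in every
sample (ties split their unit mass equally over the compatible
orderings). Each class gets an empirical distribution over the six
permutations and the triple score is their total-variation distance
$\tfrac12 \sum_\pi |p_1(\pi) - p_2(\pi)|$. This normalisation was an
open choice: an unnormalised absolute sum would order triples
identically, but TV is bounded in $[0,1]$ and collapses exactly to the
TSP $\Delta$ when two of the orderings are merged, so scores are
comparable across the pair and triple families. Classification looks
up the new sample's ordering in both class distributions; sample ties
are resolved by average-rank order with gene order as the final
tie-break, and an ordering unseen in training falls back to the larger
training class (then class 1).

**k-TSP.** All pairs are ranked by $(\Delta, \gamma)$; a greedy scan
accepts pairs whose genes are both unused ("each gene may appear in
only one pair") up to $k$. $k$ is restricted to odd values so the
majority vote cannot tie, and is selected by stratified internal
cross-validation in which the gene filter and the pair ranking are
refit inside every inner fold — selecting $k$ on pair lists fitted to
the full training set would bias $k$ upward. Ties in inner MCC go to
the smallest $k$, favouring the simpler signature.

**DIRAC.** For a network of $n_g$ genes, the class rank template
records, for each of the $\binom{n_g}{2}$ gene pairs, which gene is
higher in strictly more than half of that class's samples; a fraction
of exactly $1/2$ yields bit 0, making templates deterministic for even
class sizes. A sample's rank matching score against a template is the
fraction of pairs it agrees with (a tied pair agrees with neither
orientation). Networks are ranked for selection by their apparent
training classification rate under the two-template rule, and the top
$m$ vote on new samples; a network whose two template scores tie
abstains. The within-class mean matching score (the rank conservation
index) is also exposed, as is the full network ranking, for the
conservation-profiling style of analysis, but selection uses the
classification rate because classification is this package's goal.

**Gene filter.** TSP, k-TSP and TST scale as $G^2$ or $G^3$ in the
number of genes, so they are normally run on the top-$n$ genes ranked
by a two-sample Mann–Whitney (Wilcoxon rank-sum) separation statistic
$|U - n_1 n_2/2|$, with tied cross-pairs counted $1/2$. Two points
deserve emphasis. First, the tradition in this literature names the
*signed-rank* test here, but that test requires paired observations;
class-partitioned expression samples are independent groups, so the
rank-sum form is the defensible statistic and is what this package
computes. Second, the filter is refit inside every cross-validation
training fold; filtering once on the full dataset before CV leaks
held-out information into feature selection and inflates accuracy
estimates. The score is kept as the centred count rather than a
p-value because only the induced gene ranking matters for top-$n$
selection. DIRAC never uses this filter — its gene sets are given, and
filtering inside pathways would change their meaning.

## Evaluation

Class 1 is the positive class. Accuracy is reported alongside the
Matthews Correlation Coefficient

$$\mathrm{MCC} = \frac{tp\,tn - fp\,fn}
{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}} \in [-1, 1],$$

which, unlike raw accuracy, is chance-corrected under class imbalance.
When a denominator factor is zero (e.g. a degenerate classifier that
puts everything in one class) the MCC is defined as 0; this is the
standard convention and also keeps the adaptive module's score mapping
total. Cross-validation is repeated stratified k-fold (defaults: 10
folds, 10 repeats): folds balance the classes to within one sample —
plain k-fold on small cohorts routinely produces single-class training
folds — and each repeat pools its fold predictions into one confusion
matrix before computing MCC, because fold-level MCC on two-sample
folds is unstable or undefined. Means and standard deviations are
taken across the repeats. Fold assignment for repeat $r$ is seeded
with `seed + r`, so results are exactly reproducible.

## Adaptive configuration search

The tunable dimensions are few but consequential: the filter size for
the pair/triple searches, $k_{\max}$ for k-TSP, and the minimum
network size and network count for DIRAC. The adaptive module
enumerates Algorithm-Parameter Configurations (APCs) over a grid
(defaults: filter sizes 25/50/100/200, with the cubic TST search
capped at 200; $k_{\max} \in \{5, 9\}$; DIRAC `min_size` in
$\{3, 5\}$ crossed with $m \in \{1, 3, 5\}$) and schedules them by the
score

$$\delta(x) = \frac{t(x)}{\prod_{y \in X} \alpha(y)},$$

where $t(x)$ is the APC's deterministic abstract cost estimate
(dominant-loop counts: $n^2 M$, $n^3 M$, or pairwise template work for
DIRAC — abstract units rather than wall-clock, so schedules are
hardware-independent and reproducible), $X$ is the set of *previous
runs of the same algorithm*, and $\alpha(y) = (\mathrm{MCC}_y + 1)/2$
clamped to $[10^{-6}, 1 - 10^{-6}]$. The APC with the smallest
$\delta$ runs next; after each run its algorithm's $\alpha$ is
appended and the cost deducted from the unit budget; the search stops
on budget exhaustion, grid exhaustion, or the first run reaching the
target MCC (default 1, i.e. perfect cross-validated MCC — a
`target_mcc` argument generalises this).

The division in $\delta$ is a deliberate design decision and deserves
a note. A scheduler of this kind is described by three behaviours:
preference for cheap configurations, for algorithms that have run less
often, and for algorithms that scored well when they ran. With
$\alpha \in (0,1)$ and smallest-$\delta$-first selection, only the
quotient form satisfies all three (each extra factor raises $\delta$;
a larger past $\alpha$ lowers it). The product form
$t \cdot \prod \alpha$ — which one also encounters written down for
schedulers of this family — inverts the last two behaviours, rewarding
frequently-run, badly-scoring algorithms. Both forms are implemented
(`delta_score(..., rule = "literal")` selects the product) so the
behaviour is a documented, testable choice rather than a silent one;
the quotient is the default and is what `adaptive_search()` uses
unless told otherwise.

## Data acquisition

CSV tables (fixed dialect: genes in rows, mandatory header, first
column `gene_id`, period decimals), GDS-style SOFT files (subset
blocks with cohort tags plus the delimited dataset table; blank or
`null` cells are parse errors, not imputation targets), and MSigDB GMT
gene-set files are supported, plain or gzipped. SOFT cohort tags drive
batch class assignment (`assign_classes_by_cohort()`), mirroring the
usual two-cohort GEO workflow; samples under neither class are
excluded from all training. Multi-dataset merging intersects exact
gene identifiers in the first dataset's order — no probe-to-gene
translation is attempted, because collapsing rules are
platform-specific and lossy; probes that map to the same symbol stay
distinct. All parse errors name the offending line. Writers print
doubles with 17 significant digits so that write-then-read round
trips are bit-exact.

## The synthetic data generator

Validation runs entirely on generated data, so the generator is
first-class code, not a test fixture. It emulates a curated two-cohort
expression comparison at desk scale: per-gene baselines drawn
uniformly from [4, 10] (a log2-intensity-like scale), additive
Gaussian noise with `noise_sd` (default 1), and a configurable number
of samples per class (default 20, the order of the smaller GEO cohort
comparisons this family of methods is used on). Three planted signal
types match the three classifier families:

* `pair_reversal(i, j, gap)` sets gene *i*'s class means to gene *j*'s
  $\pm$ `gap`. With `gap` at 6 noise SDs a per-sample reversal
  misorders with probability $\Phi(-6/\sqrt2) \approx 10^{-5}$. The
  canonical validation fixture uses `gap = 12` noise SDs: the planted
  gene then clears not only its partner but the entire background
  envelope, so *every* reversal pair involving it orders decisively
  and repeated cross-validation is exactly perfect rather than almost
  so.
* `triple_cycle(i, j, k)` gives class-1 samples orderings from the
  three cyclic permutations and class-2 the three anti-cyclic ones,
  with a value ladder spaced 6 noise SDs. The permutations are
  assigned in balanced round-robin proportion within each class (then
  shuffled across samples) rather than drawn independently: the
  marginal assignment per sample is still uniform over the class's
  three permutations, but every permutation is guaranteed
  representation in every cross-validation training fold, which an
  independent draw only achieves with high probability. This
  construction is the cleanest pair-versus-triple separation
  instance: by enumeration, no pair within the triple can exceed
  $\Delta = 1/3$, while the triple's TV score is 1. It is also a pure
  relative signal — each triple gene has the *same* marginal
  distribution in both classes, so the Mann–Whitney filter cannot see
  it; TST validation therefore runs unfiltered on a small gene panel
  (15 genes).
* `network_rerank(name, genes)` gives the network a fixed descending
  value ladder in class 1 and its reverse in class 2 (step 6 noise
  SDs), plus decoy networks of background genes.

Signals may not share genes, and everything is deterministic given the
spec's seed. A `lognormal` option exponentiates the values (base 2) to
mimic raw intensity scale; since every method is rank-based this
changes nothing downstream, which is itself a tested property.

What the generator does *not* emulate: probe-level effects, batch
structure, correlated co-expression backgrounds, missing values, or
heavy-tailed noise. Passing the planted-recovery suite therefore shows
algorithmic correctness — the implementations find exactly the
structures they are defined to find, at the stated effect sizes — not
field performance on real microarray data, which depends on biology
supplying reversals of sufficient size.

## Numerical and degenerate-input choices

* Ties: expression ties get average ranks; tied pairs contribute $1/2$
  to ordering probabilities and to the Mann–Whitney count; tied
  samples split triple-ordering mass equally over compatible
  permutations; a tied pair matches neither DIRAC template
  orientation; template fractions of exactly $1/2$ give bit 0.
* Tie cascades: pair selection orders by $(\Delta, \gamma$, gene
  positions$)$; triples and networks fall back to lexicographic /
  collection order. Because these scores are ratios of small counts,
  they are compared after rounding to 9 decimals — algebraically
  equal scores reached by different floating-point paths must compare
  equal or the cascade is nondeterministic.
* Prediction ties: equal pair values, unseen orderings, tied template
  scores and tied votes all resolve to the larger training class, then
  class 1 — one rule everywhere.
* Degenerate inputs: constant genes are retained (they never win a
  reversal; dropping them silently would change gene indices);
  datasets need both classes non-empty before training, at least 2
  (TSP/k-TSP), 3 (TST) genes, or one sufficiently large network
  (DIRAC); a class smaller than the fold count lowers the fold count
  to the class size with a message; a class with fewer than 2 samples
  is an error.
* Missing values are rejected at parse time, never imputed.

## Problem sizes used in validation

The shipped test-suite and acceptance script exercise: oracle
equivalence against independent brute-force enumerators on 200 random
datasets each for the pair search (up to 30 genes, 20 samples) and the
triple search (up to 12 genes); planted-recovery fixtures of 100/15/60
genes with 20 samples per class under 10 runs of 10-fold
cross-validation; and null datasets of 40 samples. These sizes were
chosen so the full suite runs in well under a minute per module on one
CPU while still covering every tie path and the full pipeline
end-to-end.

## Known limitations

* Two classes only; multi-class problems must be decomposed outside
  the package.
* Merging requires shared gene identifiers; cross-platform analyses
  need identifiers harmonised upstream.
* The DIRAC network selection metric is the apparent training
  classification rate, which is optimistic on small cohorts; judge
  generalisation by the cross-validated MCC, never by the training
  rate.
* TST is cubic in the filtered gene count; the default grid caps it at
  200 genes, and raising that cap is rarely wise — beyond the cost,
  very large searched spaces overfit small cohorts.
* The adaptive cost model counts dominant-loop work, not constants; it
  ranks configurations sensibly but is not a wall-clock predictor.
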