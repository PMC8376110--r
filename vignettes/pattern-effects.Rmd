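---
title: "Expected Pattern Effects: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected Pattern Effects: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternEffect)
```

## The problem

Multi-task sequence models trained on chromatin accessibility or
transcription-factor binding learn which DNA patterns drive activity in each
cell type or condition, but the trained network does not expose that
knowledge directly. `patternEffect` interprets such models by *in-silico
pattern insertion*: place a concrete pattern — a motif consensus, a sampled
binding site, or a motif pair at a fixed spacing — into background sequences,
and measure how the model's class-specific predictions respond.

## The effect statistics

Let $f_c : x \mapsto y_c$ be a trained multi-task classifier giving the
probability that window $x$ is active in class $c$, and let
$x_1, \dots, x_M$ be background sequences approximating the natural sequence
distribution. For a pattern $p$, write $x_m^p$ for background $m$ with $p$
substituted at the insertion site (centered by default). The **Expected
Pattern Effect** is the mean prediction ratio

$$\alpha_c^p = \frac{1}{M} \sum_{m=1}^{M} \frac{f_c(x_m^p)}{f_c(x_m)},$$

so $\alpha > 1$ means the pattern increases predicted activity for class
$c$. Significance comes from the normalized Wilcoxon signed-rank statistic of
the per-sequence log2 ratios,

$$W = \frac{1}{M} \sum_{m=1}^{M}
  \mathrm{sign}\!\left(\log_2 \frac{f_c(x_m^p)}{f_c(x_m)}\right) R_m,$$

with $R_m$ the rank of the absolute log2 ratio. The **Differential Expected
Pattern Effect** contrasts two classes through per-sequence differences of
log2 ratios,

$$\mathrm{DEPE}(c_1, c_2) = \frac{1}{M} \sum_{m=1}^{M}
  \log_2 \frac{f_{c_1}(x_m^p)}{f_{c_1}(x_m)} -
  \log_2 \frac{f_{c_2}(x_m^p)}{f_{c_2}(x_m)},$$

with $W$ computed on those differences. The ratio form is the method's
answer to class imbalance: each class's baseline prediction level divides
out, so effects are comparable between classes whose priors differ.

Why a signed-rank test: the per-background log ratios are paired (same
background with and without the pattern), not normally distributed, and few
in number; the Wilcoxon signed-rank null is the standard nonparametric
choice for exactly that situation. Zeros are dropped before ranking (the
standard zero-handling rule) but $M$ in the $1/M$ normalization stays the
original count, so a pattern that moves only a few backgrounds is penalized.
P-values use the exact null for at most 25 tie-free non-zero pairs and a
normal approximation with continuity and tie corrections beyond that; both
regimes are recorded in the result.

In screens over a motif panel, p-values are Bonferroni-corrected across the
number of motifs tested (Benjamini–Hochberg is available); the divisor is
the panel size, not panels × class-pairs, matching per-comparison reporting.

## The model

The predictor is an ensemble of small multi-task convolutional networks,
implemented natively in this package (im2col patch matrices multiplied
through BLAS, so the heavy computation is dense linear algebra):

* one-hot input (window length × 4, `N` encoded as uniform 0.25),
* a first convolution layer whose filters can be initialized from motif
  log-odds $\log_2((p + 0.01)/0.25)$, centered within the filter width,
* ReLU, a member-specific second convolution layer, ReLU,
* global max pooling over positions (the network keeps only each feature's
  maximally activating position, making responses largely
  translation-invariant),
* a dense sigmoid head with one output per class.

Members differ in their second-layer shape so the ensemble scans for motif
combinations at several receptive-field sizes; ensemble predictions are the
equal-weight mean of member probabilities. Training minimizes multi-task
binary cross-entropy with Adam, stops early when validation loss fails to
improve for `early_stopping_patience` epochs (default 2), and restores the
best-epoch weights. All randomness derives from the configuration seed
(member $i$ uses `seed + i`), so runs are reproducible. The output head is
initialized near zero so that initial predictions sit near 0.5 regardless of
the scale of motif-initialized convolution activations.

Package defaults (64 first-layer filters of width 17; five members with
second layers (8,5), (16,9), (32,13), (64,17), (128,21); 5 epochs; batch
256; Adam at 1e-3) are stand-ins for a published full-scale configuration
and every field of `model_config()` is open. The test fixtures in this
package use a deliberately small configuration — 16 motif-initialized
filters of width 12 (17 for spacing grammars), two members with second
layers (8,5)/(16,9), batch 64, learning rate 3e-3 — sized so that a model
trains in tens of seconds on one CPU while still recovering planted
grammars.

## Tunable parameters that matter

* `window_length` (bp, default 100): all sequences, backgrounds and
  patterns live in windows of this size.
* `M` (default 24): background-set size. Larger $M$ tightens the
  signed-rank null (exact p-values resolve to $2^{-M+1}$) and stabilizes
  $\alpha$; the default mirrors the method's standard study size.
* insertion `position` (0-based, default `floor((L - len)/2)`): effects are
  stable for central insertions and distorted very close to the sequence
  start, so centered insertion is the default.
* clipping `epsilon` (default 1e-6): predictions are clipped to
  $[\epsilon, 1-\epsilon]$ before ratios and logs, preventing division
  blow-ups; for predictions in $[10^{-4}, 1-10^{-4}]$ the clip provably
  changes nothing (asserted in the tests by recomputation at
  $\epsilon/10$).
* labeling rule: a genome window is labeled active for a class when
  strictly more than half of its length is covered by the union of that
  class's regions. Union semantics make labels invariant to how region
  sets are fragmented or ordered.
* splitting: validation and test sets are whole held-out chromosomes
  (defaults chr18 / chr19), so evaluation windows share no local sequence
  context with training windows.

## The synthetic-data generator

The generator emulates the data structure these analyses assume: fixed-length
windows; multi-hot labels; class-specific grammars (single motifs or motif
pairs at a fixed gap) embedded with per-grammar probability at the window
center plus uniform jitter; i.i.d. background at a configurable GC;
all-zero-label negative windows (default half of the mean per-class positive
count); and round-robin fake chromosomes so held-out splitting is exercised.
Several grammars may share a class, each embedded independently, which
produces classes with graded motif repertoires. Embedded instances are drawn
from the PWM rather than fixed at the consensus, so recovery is not trivial
string matching. A ground-truth table records every embedded instance and
its position.

Decoy panels for screens are random sharp PWMs plus column-shuffled versions
of the embedded motifs, all constrained to at most half-length consensus
identity against every embedded motif at any ungapped alignment offset. The
constraint is a validity requirement, not a convenience: an unconstrained
"decoy" that happens to align to a planted motif at 5–6 of 8 positions draws
a genuinely learned response — it behaves like a same-family motif, which in
real screens shows up as a legitimate hit, not a false positive.

What the generator does **not** emulate: repeats, CpG islands, dinucleotide
structure, chromatin domains, or correlated peak shapes. Passing recovery
tests therefore shows that the pipeline is correct and sensitive under clean
conditions; it does not certify performance on real genomes.

## Study sizes used by the tests and acceptance script

Chosen once as the smallest sizes at which recovery is reliable on one CPU:
the two-class motif-recovery study uses 1500 positives per class plus 750
negatives (window 100 bp, embed probability 0.9, jitter ±10); the
spacing study uses 500 positives per class with motif pairs at gaps 3 vs 8
(the competing class makes spacing itself the discriminative signal, a
design that mirrors preferred versus non-preferred co-binding geometry); the
imbalance study uses 400/400 versus 400/4000; model-contract checks use
1000 per class at embed probability 0.95.

## Numerical choices

* Exact signed-rank p-values come from the exact Wilcoxon null distribution;
  the tests cross-check them against full enumeration of all $2^m$ sign
  assignments.
* AUROC is computed by the rank (Mann–Whitney) formula with average ranks
  for ties; a constant predictor scores exactly 0.5. Average precision sums
  precision at each positive in decreasing-score order. Classes with a
  single label value report `NA` rather than erroring.
* Consensus reduction breaks PWM ties by fixed base order A<C<G<T, so it is
  deterministic; PWM-sampled reduction is provided for sensitivity checks.
* Wildcard spacer positions (`*`) in paired patterns keep the background
  base, so a spacing scan measures geometry rather than spacer content.
* Insertions never change sequence length; the pattern overwrites the
  background in place.
* Saved models restore bit-identical predictions (weights serialize
  losslessly); training determinism holds for a fixed seed on a fixed BLAS.

## Known limitations

* The ensemble is a deliberately small stand-in for GPU-scale accessibility
  models; absolute effect sizes from fixture-scale models are not calibrated
  to any real biology.
* Any insertion perturbs the window center, and a trained model can respond
  to that perturbation itself with a small class-asymmetric offset shared by
  all patterns. With $M = 24$ backgrounds and exact signed-rank p-values,
  such an offset can push null patterns past Bonferroni significance in
  some training runs. Screens are therefore best read relative to the
  panel's effect distribution — the strongest positive and negative effects
  and their separation from the bulk — rather than as absolute significance
  calls.
* One-vs-rest DEPE uses the mean predicted probability of the remaining
  classes as the comparator; with heterogeneous "rest" classes this blurs
  class-specific structure.
* Reverse-complement handling is off by default (forward-strand biology);
  `both_strands` scores each background by the better of the two
  orientations, which is a max statistic and slightly anti-conservative.
* At fixture scale, the rank-order stability advantage of ratio-based
  effects over difference-based effects under class imbalance — the
  motivation for the ratio form — is not resolvable: across repeated
  balanced/imbalanced pairs, Spearman correlations of the two estimators are
  statistically indistinguishable, because retraining variability dominates
  the baseline-shift distortion that the ratio removes and the rank metric
  discards the value-scale distortion that the ratio demonstrably avoids.
  The corresponding check in `tests/testthat/test-acceptance.R` encodes the
  expected full-scale behavior and currently fails at fixture scale; the
  `gia_effect()` comparator is retained precisely so users can reproduce
  this comparison at their own scale.
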