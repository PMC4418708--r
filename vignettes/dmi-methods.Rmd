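---
title: "Predicting domain-motif interactions with naive Bayes likelihood ratios"
author: "dmibayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting domain-motif interactions with naive Bayes likelihood ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmibayes)
```

## The model

`dmibayes` scores protein pairs for interactions mediated by a
peptide-recognition domain (PRD) on one protein binding a short linear motif
(SLiM) on the other. The statistical core is a naive Bayes likelihood-ratio
scheme. For each observable property ("clue") $c_i$ of a candidate
domain-motif interface, the likelihood ratio

$$LR(c_i) = \frac{P(c_i \mid \mathrm{TP})}{P(c_i \mid \mathrm{TN})}$$

is estimated by exhaustive counting over a curated true-positive pair set
(size $N_{TP}$) and a true-negative pair set (size $N_{TN}$):
$P(c_i \mid \mathrm{TP}) = n / N_{TP}$ where $n$ is the number of TP pairs
observed with the clue.

Two discovery routes produce candidate interfaces, with different clue sets:

* **PRD/motif** (consensus route): clues are the presence of a class match
  (*match*), the class identity (*class*), motif disorder (*diso*) and motif
  local conservation (*consv*). The latter three are conditional on *match*
  being true, so each is normalized by $LR(match)$:
  $$LR(\mathrm{DMI}) = LR(match) \cdot \frac{LR(class)}{LR(match)} \cdot
    \frac{LR(diso)}{LR(match)} \cdot \frac{LR(consv)}{LR(match)}$$
* **Struct** (template route): clues are *match*, the structural-distance
  bin (*PSD*), the sequence-similarity bin (*SIM*), *diso* and *consv*, with
  the four conditional clues normalized the same way:
  $$LR(\mathrm{DMI}) = LR(match) \cdot \frac{LR(PSD)}{LR(match)} \cdot
    \frac{LR(SIM)}{LR(match)} \cdot \frac{LR(diso)}{LR(match)} \cdot
    \frac{LR(consv)}{LR(match)}$$

The implementation evaluates the normalized products literally;
`tests/` verify against the algebraic reductions
$LR(class) LR(diso) LR(consv) / LR(match)^2$ and
$LR(PSD) LR(SIM) LR(diso) LR(consv) / LR(match)^3$ to $10^{-12}$ relative
tolerance.

A pair's aggregated DMI evidence is the **maximum** LR over its candidate
interfaces (see *Design choices*), multiplied by a pre-computed
non-structural evidence LR. With prior odds $\pi$ of interaction, the
posterior probability is $LR \cdot \pi / (1 + LR \cdot \pi)$; at the default
$\pi = 1/600$ a final LR of 600 gives exactly 0.5, which motivates the
strict LR > 600 rule for "strong predictions".

Key naive Bayes assumption: clues are conditionally independent given the
interaction status (and given the match, for the conditional clues). This is
an approximation — disorder and conservation of the same motif are
correlated in real proteomes — and is the main modelling caveat inherited by
every LR product.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| contact distance | 4.5 | Å | PRD residue is interfacial if any atom is within this distance of the peptide (inclusive) |
| ASA threshold | 10 | Å² | residue is surface-exposed at or above this accessible surface area |
| probe radius | 1.4 | Å | water probe for Shrake–Rupley ASA |
| interface coverage | 0.75 | fraction | minimum share of template interfacial residues aligned to surface residues (inclusive) |
| PSD bins | 0.3, 0.65 | — | P1 = [0, 0.3], P2 = (0.3, 0.65); ≥ 0.65 rejected |
| top fraction | 5e-4 | fraction | window-scan retention (top 0.05 % of all windows) |
| similarity bins | 1e-6, 1e-5, 1e-4, 5e-4 | fraction | B1–B4 rank-fraction boundaries (right-closed) |
| peptide length | 5–35 | residues | usable template peptides (inclusive) |
| disorder cutoff | 0.5 | score | motif disordered iff mean per-residue score strictly exceeds it |
| conservation window | 31 | residues | neighbourhood half-width for the local-conservation test |
| strong threshold | 600 | LR | strict `>` comparison |
| `alpha` | 0 | count | additive smoothing pseudocount in LR estimation |
| `lr_cap` | 1e6 | LR | bound for clues never observed among true negatives |

All of these sit in one place (`run_config()`) and default to the published
operating points; `alpha` and `lr_cap` govern zero-cell behaviour the source
method leaves unspecified (see below).

## Numerical and edge-case choices

* **Inclusive boundaries.** "Within 4.5 Å", "cutoff of 10 Å²" and "at least
  75 %" are read as closed comparisons; disorder ("larger than 0.5") and
  local conservation ("higher than") are strict. A PSD of exactly 0.3 falls
  in P1 (closed lower bin).
* **Percentile ties.** The window-scan cutoff is the score of the
  $\lceil f N \rceil$-th best of $N$ windows; every window scoring at least
  that is retained, which makes the rule deterministic and order-independent.
  Because BLOSUM62 scores are integers, boundary ties can push a retained
  window's rank fraction past $f$; such windows keep their scores but get no
  similarity bin (`NA`) and therefore contribute no Struct candidate.
* **Overlapping consensus matches** are enumerated by attempting the regular
  expression at every start position; a leading `^` restricts matching to
  position 1 and `$` keeps its end-of-sequence meaning.
* **Zero cells.** With `alpha = 0`, a clue never seen among TPs has LR 0; a
  clue never seen among TNs would be infinite and is capped at `lr_cap`
  (1e6) and flagged. The cap preserves ranking without infinities. A
  (clue, value) never seen in training at all scores the neutral LR 1 at
  prediction time.
* **Missing NS evidence** multiplies as LR 1 (the multiplicative identity),
  so pairs without auxiliary data are neither rewarded nor penalized, and
  evaluation denominators stay fixed across methods.
* **ASA sampling** uses a deterministic golden-spiral point set (960 points
  per atom), so repeated runs are bit-identical and translations leave
  values unchanged; rotations re-sample occlusion within the ~2 % sampling
  tolerance (tests pin the isolated-sphere and two-sphere closed forms at
  2 %). Van der Waals radii: C 1.70, N 1.55, O 1.52, S 1.80 Å, 1.80 Å with
  a warning for anything else. Only the first `MODEL` of a multi-model PDB
  file and altLoc `''`/`A` atoms are used; `HETATM` records are ignored.
* **`X` rule.** Non-standard residue letters map to `X`, which scores 0
  against everything in window scoring and is excluded from the
  amino-acid frequency distribution (while still counting as non-gap) in
  conservation columns.
* **Local conservation window** excludes the centre residue from the
  neighbourhood mean — otherwise a residue could never beat a window
  containing itself at uniform conservation — and truncates at sequence
  ends; a single-residue protein is never locally conserved; tied scores are
  not conserved (strict inequality).
* **ROC/PR**: tied scores collapse to one threshold step; ROC area by
  trapezoid (equal to the concordance statistic with ties counted ½,
  verified against a pair-counting oracle); PR area by the uninterpolated
  step integral.

## Design choices where the method was genuinely open

* **Aggregation over multiple interfaces per pair = max.** The per-pair
  maximum is specified only for scoring a competing tool's output, but the
  same "larger of the two" convention governs merging with the original
  domain-domain structural LR, so the maximum is adopted for this package's
  own predictions too; the two routes frequently describe the same physical
  interface, and multiplying would double-count it. A `policy = "product"`
  switch exists for comparison.
* **Combination of the PRD/motif and Struct routes** is likewise the max
  over both routes' interfaces, realized by aggregating their matches
  together.
* **$LR(match)$ is estimated pooled per method**, not per template or per
  class; the class/template identity enters through the *class* (or a
  template-identity) clue instead.
* **Window-scan percentiles are per template**: each template's windows are
  ranked among all windows of that template's length, which is what makes
  scores comparable across templates of different lengths.
* **Cross-validated curves pool held-out scores** across folds into a single
  ROC/PR rather than averaging per-fold curves, matching a single-curve
  presentation.
* **Unstratified folds**: the k-fold split partitions TP and TN pairs
  independently and uniformly at random under the given seed.
* **Redundant or overlapping domain annotations** are consumed as given; no
  resolution policy is applied.

## What the synthetic generator emulates — and what it does not

`synth_config()` fixes the study conditions for all seeded generators:

* **Clue-frequency planting** (`generate_training_sets()`): each TP pair
  carries a candidate interface with probability 0.5 (consensus route) or
  0.3 (template route) versus 0.05 / 0.03 for TN pairs; carried interfaces
  draw disorder flags at 0.7 vs 0.3, conservation at 0.6 vs 0.3, PSD bin P1
  at 0.7 vs 0.3, and similarity bins from shifted distributions. NS LRs are
  log-normal with median 20 (TP) vs 1 (TN), dispersion `sdlog = 1`. The
  default training size is 2,000 TP + 2,000 TN pairs — large enough that
  the null cross-validated AUC concentrates within ±0.05 of 0.5 while a
  50-replicate null scan stays fast. Setting `signal = FALSE` copies every
  TP parameter onto its TN counterpart, the permutation-null condition.
* **Sequence-level fixtures** (`generate_proteome()` and friends): a 24
  protein proteome (350–500 residues) with motif strings spliced in at
  recorded positions, disorder tracks at 0.7 ± 0.08 on planted motifs versus
  0.3 ± 0.08 background, 8-row ortholog alignments with 2 % substitution on
  motif columns versus 50 % plus 10 % gaps elsewhere, idealized CA+CB
  template complexes placed at an exact minimum atom-atom gap, and jittered
  candidate-model structures. The proteome size is chosen so that a planted
  peptide's few verbatim copies still rank inside the top 0.05 % of scanned
  windows, i.e. the percentile machinery is exercised end to end.
* All randomness flows from one master seed through per-generator derived
  streams, so adding a generator never perturbs existing output.

Passing tests on these fixtures demonstrates that the machinery — counting,
normalization, filters, binning, cross-validation — is correct under known
ground truth. It does **not** demonstrate performance on real proteomes:
real motifs are not uniform-background splices, real clue dependencies
violate conditional independence, real structural alignments have partial
and noisy correspondences, and real TN sets are contaminated with
undiscovered interactions (which is why a reported false-positive rate is
only an upper bound — a property the test suite asserts directly on
synthetic contamination).

The toy structural-distance values attached to synthetic alignments are
drawn uniformly and are *not* equivalent to distances from a real structural
aligner; they exist to exercise the binning and filtering logic.

## Problem sizes and runtimes

The test suite runs the full matrix in well under a minute on one CPU:
clue-LR counting oracles at up to a few hundred pairs per configuration (100
configurations in the acceptance suite), planted-LR recovery at 10,000 +
10,000 pairs across 20 seeds, a 50-replicate null cross-validation at 2,000
+ 2,000 pairs per replicate, and window-scan oracles on proteomes of at most
1,000 residues. `scripts/acceptance.R` re-derives the headline quantities in
a few seconds.

## Known limitations

* Domain annotations, disorder scores, ortholog alignments, structural
  alignments (with their PSD values) and NS likelihood ratios are consumed
  as inputs; the external tools that produce them are out of scope.
* The naive Bayes independence assumption is not checked against the data;
  correlated clues inflate combined LRs.
* The LR cap (1e6) is arbitrary below infinity; capped clues are flagged so
  downstream users can treat them separately.
* ASA is computed on the candidate model in isolation; crystal-packing or
  complex partners that would bury the interface are not modelled.
* Consensus patterns with a `^` inside alternations are matched with
  start-anchored semantics only at position 1.
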