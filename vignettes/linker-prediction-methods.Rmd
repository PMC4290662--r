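---
title: "Methods: per-residue linker prediction from windowed physiochemical profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-residue linker prediction from windowed physiochemical profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkerforest)
```

## The problem and the model

Multi-domain proteins consist of independently folding domains (25–500
residues) joined by short, flexible inter-domain linkers (10–100
residues). `linkerforest` treats linker identification as a binary
per-residue classification problem: every residue is an instance, *linker*
is the positive class, and the classes are severely imbalanced (domains
hold ~95% of residues in the calibration data this package's defaults are
anchored to).

The model rests on one core assumption: linkers and domains differ in
amino-acid *composition*. Linkers are enriched in small, polar, flexible
residues (P, S, T, E, K) and depleted in hydrophobic core-forming ones
(W, C, G, Y). The **linker-propensity index** condenses this into one
number per amino acid,

$$S_i = -\ln\left(\frac{f_i^{\mathrm{linker}}}{f_i^{\mathrm{domain}}}\right),$$

with $f$ the percentage frequencies in each partition; negative values mark
linker preference. Because a single residue's identity is far too noisy a
signal, the per-residue encodings (index, hydrophobicity, and five
categorical side-chain properties) are averaged over a sliding window
centred on each residue, and the windowed vectors are classified by a
random forest. The forest votes per residue; no class weighting or
resampling is applied anywhere — robustness to imbalance is a property
being evaluated, not engineered around.

## Feature encoding

The seven feature groups are concatenated in a fixed order (`linker_index`,
`hydrophobicity`, `charge`, `polarity`, `aromaticity`, `size`,
`electronic`). Choices that were genuinely open, and how they were fixed:

* **Categorical encoding.** The categorical properties have no natural
  numeric scale, and window-averaging requires numbers. One-hot encoding
  before averaging is the default because the windowed values then have an
  exact interpretation — within-window category fractions — and no
  information is destroyed by an arbitrary ordering. An `ordinal` option
  (one integer-coded column per property) exists for ablation parity.
* **Hydrophobicity scale.** SARAH1 (a unique signed five-bit code per
  residue, exactly two non-zero entries, ranked by Rose hydrophobicity) is
  the default; the kcal/mol (pH 7) and Rose scales are selectable
  single-column alternatives. The packaged kcal/mol table stores K as
  +5.55 exactly as printed in its source; its position between Q (−5.54)
  and N (−6.64) in the polar half suggests a missing minus sign, and the
  data file flags this rather than silently correcting it.
* **Index source.** Whether the propensity index should be re-estimated on
  each training fold or taken from the packaged reference table is not
  decidable from first principles; both are supported
  (`linker_index_source`), and per-fold estimation is the default because
  it is the leakage-free choice.

## Window averaging

For residue $j$ of a length-$L$ sequence, the profile row is the mean of
the raw encoding rows over positions
$\max(1, j - (w-1)/2) \dots \min(L, j + (w-1)/2)$, i.e. the window is
clipped at both termini and the denominator is the number of positions
actually included. This is the only self-consistent reading of the
three-case piecewise definition the formulation is usually given in (whose
printed interior bounds and terminal denominators contradict each other at
one boundary); it reproduces the interior case and both terminal
denominators exactly. `window_average()` implements it by cumulative sums;
the test suite checks it against a brute-force per-position loop for all
odd $w$, including $w$ larger than the sequence (every position then
averages the whole sequence) and $w = 1$ (identity).

The default window is $w = 41$, the size at which recall, precision and
F-measure peak in window sweeps on the calibration datasets;
`sweep_window()` re-runs that sweep on any corpus.

## The forest

Defaults follow the standard random-forest recipe: 200 trees (beyond which
accuracy gains stop justifying compute), bootstrap samples of size $N$
drawn with replacement, $m = \lfloor\log_2 M\rfloor + 1$ features drawn
uniformly at each node (5 for the default $M = 22$), Gini impurity splits,
trees grown until pure. The ensemble is fitted by `ranger`, pinned to
exactly this recipe and verified by the tests (seeded determinism,
vote-fraction granularity $1/n_\mathrm{trees}$, reduction to a single
unbagged tree, out-of-bag error on a separable toy task).

Numerical conventions:

* **Vote tie-break.** A residue is called linker when its vote fraction is
  `>=` the threshold (default 0.5), so an exactly split even ensemble goes
  to linker — a fixed, testable rule rather than a random one.
* **Segment filtering.** `min_linker_run` (default 0) optionally suppresses
  predicted linker runs shorter than a minimum; it is off by default
  because the evaluation metrics are per-residue.
* **Pseudocount.** With pseudocount 0 (the default), an amino acid observed
  in exactly one partition would give an infinite index; this errors with a
  message recommending a positive pseudocount rather than propagating an
  infinity. Corpora small enough for a rare residue to vanish from one
  partition — including 10-fold training splits of ~100-sequence corpora —
  should use a small positive value; the package's evaluation runs use
  0.01.

## Evaluation protocol

`score_predictions()` pools residue-level confusion counts (TP: linker
residues called linker; TN: domain residues called domain; and so on) into
accuracy, recall, precision and F1. Ratios with zero denominators are
reported as 0 with an explicit `zero_division` flag so aggregate tables
stay totals-safe. `cross_validate()` splits **sequences**, never residues,
into folds: windowed features of neighbouring residues overlap, so
residue-level splitting would leak test information into training and
inflate every metric. Both fold-mean and pooled metrics are reported, since
published figures of this kind rarely state which aggregation they used.

`information_gain()` ranks features by C4.5-style best-binary-split entropy
reduction (in bits) — parameter-free, invariant under monotone feature
transforms, and the natural companion to impurity-based trees.
`ablate_groups()` aggregates per-feature IG to the seven groups (mean over
member columns) and re-runs cross-validation while removing groups — either
cumulatively in ascending-IG order (mirroring published ablation tables) or
one-at-a-time (`scheme = "single"`), which isolates each group's marginal
contribution and is what the package's own acceptance checks use to
contrast the linker-index and polarity groups.

## The synthetic generator

`generate_corpus()` emulates exactly the structure the propensity model
assumes and nothing more: alternating domain–linker–…–domain architecture
(2–3 domains per sequence), segment lengths from rounded Gamma laws
(shape 4; positive, right-skewed, mean-parameterizable — the available
calibration is a mean plus hard bounds) truncated by rejection to the
canonical ranges (domains: mean 147.1 in [25, 500]; linkers: mean 12.7 in
[10, 100]), and residues drawn i.i.d. from partition-specific compositions
defaulting to the packaged linker/domain frequency columns. The linker law's
lower truncation bound (10) lies close to its mean (12.7), so the realized
mean linker length is ~16; the tests compare realized means against the
truncated laws, not the raw ones. A `divergence_multiplier` scales the
log-ratio of the two compositions about their geometric mean and
renormalizes, giving a single effect-size knob for separability and
power-style experiments.

What the generator deliberately does **not** simulate: sequence-order
correlation within segments, homology between sequences, secondary
structure, or any higher-order composition statistics. Real proteins have
all of these, and real linker/domain composition differences are far
smaller than a divergence-3 corpus's. Passing end-to-end tests on
generated corpora therefore demonstrates that the pipeline recovers a
zeroth-order composition signal when one exists — not that it attains any
particular accuracy on real proteins.

## Problem sizes used by the checks

The package's own evaluation runs use: 500 sequences for composition
convergence checks; 20,000 sequences (~8M residues) for index-recovery
checks, sized so that the rarest amino acid (W, 0.89% of linker residues)
has small enough sampling error for a ±0.05 index tolerance; and 100
sequences at divergence 3 with $w = 41$, 200 trees, and 10-fold CV for the
end-to-end runs.

## Known limitations

* **Window/linker length mismatch.** When linkers are much shorter than
  the averaging window, per-residue separation hits an information limit:
  for a linker of length $\ell < w/2$, the windows centred on the linker's
  own residues and those centred on up to $w - \ell$ adjacent domain
  residues contain *identical* linker fractions, so no classifier on
  windowed composition can tell them apart. With the default corpus
  conditions (realized mean linker ~16, $w = 41$) this caps jointly
  achievable recall and precision; the same pipeline on corpora with
  longer linkers (e.g. mean 35.8) separates well. This is a property of
  the representation, not of the forest.
* **No sequence-order information.** Each residue is classified from its
  own window average alone; run-level coherence of predictions is not
  modelled (only optionally post-filtered via `min_linker_run`).
* **Composition-only features.** No evolutionary profiles and no secondary
  structure, by design; signals that only exist in those channels are
  invisible to this model.
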