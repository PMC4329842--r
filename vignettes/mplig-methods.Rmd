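---
title: "Predicting ligand-binding residues in membrane proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ligand-binding residues in membrane proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplig)
```

## The problem

Alpha-helical membrane proteins carry out transport, signalling and
energy conversion through interactions with bound ligands — hemes,
retinal, quinones, ions, substrates.  Identifying which residues line a
ligand site normally requires a solved structure; `mplig` implements a
sequence-only predictor: given a residue and its sequence neighbourhood,
classify it as ligand-binding or not.

The pipeline has four stages:

1. **Ground truth from structures.**  In a protein–ligand complex, every
   non-protein, non-water heteroatom group in contact with the protein is
   a ligand, and a residue is *binding* when the distance between any of
   its atoms and any ligand atom is lower than 4.5 Å.
2. **Window encoding.**  Each residue becomes one training example: the
   concatenated per-residue descriptors of itself and its `k` sequence
   neighbours on each side (window size `s = 2k + 1`; default `k = 2`).
   Three descriptor families are supported: amino-acid property vectors,
   BLOSUM62 rows, and PSI-BLAST PSSM profile rows.
3. **Gaussian Naive Bayes.**  A from-scratch classifier with a
   likelihood-ratio decision rule.
4. **Leave-one-protein-out evaluation** with accuracy, sensitivity,
   specificity, MCC and ROC curves.

## Binding-residue labels

`parse_structure()` reads PDB ATOM/HETATM records (via bio3d), keeps the
highest-occupancy conformer of alternate locations, excludes waters
(HOH/DOD/WAT) and groups every remaining HETATM residue into a ligand
group.  No other het group is excluded: ions and crystallisation
additives count as ligands, because the binding-site definition places
no exclusion list beyond water.  Non-standard polymer residues map to
`"X"` in the sequence but their atoms still participate in distance
checks.

The contact rule is a strict inequality (`distance < cutoff`): a pair at
exactly 4.5 Å does *not* bind.  Where "within 4.5 Å" is preferred as a
closed condition, `inclusive = TRUE` switches every contact operation to
`<=`.  `label_binding_residues()` offers two exact algorithms — an
exhaustive all-pairs scan and a default bounding-box prefilter — which
must (and, by property test, do) agree on every input.

Residue indices are 1-based and contiguous along each parsed chain, the
R convention used by the containers this package interoperates with;
author PDB numbering is retained as metadata only.

## Window encodings

For a per-residue descriptor matrix (N × P), the example for residue *t*
is the concatenation of rows *t−k … t+k* (D = s·P attributes).  Window
slots that fall off either end of the chain are *padded*:

* `padding = "mean"` (default): the per-attribute mean of the chain's
  descriptor matrix.  Under a Gaussian class-conditional model a value at
  the pooled mean carries almost no class information, so flanking
  residues are neither pushed positive nor negative.  The mean is
  computed from the chain being encoded — encoding is a per-chain
  operation and never sees the cross-validation split, so held-out
  chains are padded identically whether or not they are in training.
* `padding = "zero"`: plain zero fill, for comparison.

The three descriptor families:

* **Properties** — a 20 × 48 table of per-amino-acid values.  The
  default table (`default_property_table()`) draws from the AAindex
  collection shipped with seqinr: a curated core of classic scales
  (Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity, Grantham
  polarity, molecular weight, net charge, accessible surface area,
  residue volume, Chou–Fasman propensities, flexibility, …) topped up
  deterministically in accession order with further NA-free AAindex
  entries until 48 columns are reached.  Property sets of this kind are
  not unique; the table is an explicit input (`read_property_table()`)
  so any 20 × P table can be substituted.  `"X"` maps to the
  per-property mean.
* **BLOSUM62** — each residue is its 20-entry row of the canonical
  half-bit BLOSUM62 matrix, embedded verbatim (and cross-checked against
  Biostrings in the test suite).  `"X"` maps to the zero vector.
* **PSSM** — each residue is its 20-score row of a PSI-BLAST
  position-specific scoring matrix (`parse_pssm()` reads the standard
  ASCII dump, first score block, fixed `A R N D C Q E G H I L K M F P S
  T W Y V` column order).  PSSMs are produced externally — typically
  PSI-BLAST with BLOSUM62, 3 iterations, e-value 0.001 against a
  membrane-protein reference database — and this package only parses
  the result.

Numeric attributes are min–max normalized into [0, 1]
(`fit_normalizer()` / `apply_normalizer()`).  The normalizer is fitted
on the training fold only, never on held-out chains; whether to
normalize per fold or globally is a genuinely open design point, and the
per-fold choice is the leakage-safe one.  Constant attributes map to 0
and out-of-range test values are clipped into [0, 1].

## The classifier

Naive Bayes assumes attribute independence given the class, so for an
example $X = (x_1, \dots, x_D)$ the posterior odds factorise:

$$
\frac{P(c{=}1 \mid X)}{P(c{=}0 \mid X)} =
\frac{P(c{=}1)\prod_i P(x_i \mid c{=}1)}
     {P(c{=}0)\prod_i P(x_i \mid c{=}0)} > \theta
\;\Rightarrow\; \hat c = 1 .
$$

* Likelihoods are Gaussian per attribute per class, with sample means
  and variances from the training fold.  No kernel density estimation.
* The decision threshold θ defaults to 1; a tie (ratio exactly θ) is
  classified negative, matching the strict "greater than" of the rule.
  Sweeping θ traces the ROC curve.
* Priors are the empirical class frequencies — about 13.4 % positive in
  realistic binding-residue data — and no re-weighting is applied.  A
  `priors` argument exists for experiments that need an imposed
  decision boundary (e.g. the equal-prior Bayes-accuracy recovery test).
* Everything is computed in log space: at D = 100–240 attributes the raw
  likelihood products underflow double precision, the log-sums do not.
* Variances are floored at `max(1e-12, 1e-9 × attribute range)` so that
  an attribute constant within a class cannot produce an infinite
  likelihood ratio.

A discrete-likelihood mode (frequency tables instead of Gaussians)
exists purely as test machinery: on small categorical problems the ratio
rule is checked against exhaustive evaluation of the joint
$P(c)\prod_i P(x_i \mid c)$.

## Evaluation

`compute_metrics()` reports the confusion counts and

$$
\mathrm{Acc} = 100\,\frac{TP+TN}{N},\quad
\mathrm{Sn} = 100\,\frac{TP}{TP+FN},\quad
\mathrm{Sp} = 100\,\frac{TN}{TN+FP},
$$
$$
\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP{+}FN)(TP{+}FP)(TN{+}FP)(TN{+}FN)}} .
$$

Conventions for degenerate inputs: MCC is 0 when any denominator factor
is 0; sensitivity and specificity are `NA` (undefined, not 0) when their
own denominators vanish.

`roc_curve()` sweeps the strict-greater rule over the sorted unique
scores.  The stated threshold grid is the unique scores plus a `+Inf`
sentinel; with a strict `>` at the minimum score the curve cannot reach
(1, 1), so a `-Inf` sentinel is appended and consecutive duplicate
points are collapsed.  AUC is the trapezoid area.

`lopo_cv()` implements leave-one-protein-out cross-validation with
grouping strictly by chain: in each fold one chain is held out entirely,
the normalizer and the model are fitted on the rest, and the held-out
chain is scored.  Pooled (micro-averaged) counts over folds are the
headline numbers; the per-chain table gives the per-protein view.  A
fold whose training set loses a class is skipped with a warning rather
than silently mis-fitted.

## Synthetic data

Real training data require PDB structures and PSI-BLAST runs against a
curated membrane-protein database; neither is distributable here, so the
package ships generators that exercise every file interface:

* `simulate_structure()` writes PDB text for a poly-alanine chain (one
  CA per residue) with a single het atom at the origin; pocket residues
  sit at `pocket_distance` (default 3 Å), all others at `decoy_distance`
  (default 20 Å), each on its own random direction.  The embedded truth
  must be reproduced exactly by the contact labeller — an end-to-end
  oracle.  Coordinates are rounded to the PDB's three decimals
  (≤ 0.002 Å perturbation), so pocket and decoy distances should stay
  clear of the cutoff.
* `simulate_profiles()` emulates a PSSM-encoded dataset: 20 chains of
  500 residues by default, labels at 13.43 % prevalence (the class
  imbalance of curated membrane-protein binding-residue sets), 20
  Gaussian score columns with a class-conditional mean shift
  (`effect_size`, default 1, on columns 1–4; noise SD 1).  Gaussian
  columns deliberately match the classifier's likelihood family so
  closed forms exist: with equal priors and a shift *d* spread over *m*
  columns the Bayes accuracy is $\Phi(d\sqrt{m}/2\sigma)$, which
  parameter-recovery tests verify within ±3 points at the default 20 ×
  500 problem size.  A heavy-tailed Student-t mode exists to probe
  robustness; no closed form is claimed for it.

What the synthetic data do **not** emulate: real evolutionary profiles
(PSSM columns are correlated and residue-dependent), sequence
autocorrelation of binding sites (real binding residues cluster in
helices; synthetic labels are i.i.d.), and realistic membrane topology.
Passing the recovery tests therefore demonstrates the correctness of
the machinery — labelling, encoding, fitting, grouped CV, metrics — not
the field performance of the predictor on real proteins, which depends
on user-supplied structures and PSSMs.

## Numerical and design choices

* Strict `<` at the contact cutoff, with `inclusive = TRUE` exposed,
  because "lower than" and "within" both appear in common definitions
  of the 4.5 Å rule.
* All deposited atoms participate in distance checks, hydrogens
  included when present.
* Log-space likelihood sums; variance flooring as above; ties at θ
  negative.
* Min–max normalization per training fold; constants → 0; clipping.
* Problem sizes in the tests (20 chains × 500 residues for recovery
  checks; 50 structures for the labelling equivalence sweep) are chosen
  so each closed-form comparison has sampling error comfortably inside
  its tolerance while the whole suite stays quick to run.
* The serialized model format is versioned JSON at 17 significant
  digits, so reload reproduces every prediction bit for bit.

## Known limitations

* mmCIF files, biological-assembly expansion and symmetry mates are not
  handled; covalently bound het groups are treated like any other
  ligand.
* PSI-BLAST is not invoked; users must bring their own PSSMs for real
  sequences.
* The per-protein window-size sweep (k = 1…7) is a user exercise via
  the `k` argument, not a built-in report.
* No alternative classifiers are bundled; the Naive Bayes model is the
  point of the package, and standard R libraries cover baselines.
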