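---
title: "Position-specific statistical potentials for hexapeptide aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific statistical potentials for hexapeptide aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexamyloid)
```

## The statistical model

`hexamyloid` treats a hexapeptide as six independent positional draws. For
a labeled collection of hexapeptides, the percent composition of residue
$i$ at position $j$ is $Comp(i,j) = 100\, n_{ij} / N_j$ with $N_j$ the
number of peptides. Dividing by a background — the percent composition
$Comp_{glob}(i)$ of residues in globular proteins — gives the
position-specific propensity, and treating propensities as Boltzmann
weights gives the statistical potential in kcal/mol:

$$Propen(i,j) = \frac{Comp(i,j)}{Comp_{glob}(i)}, \qquad
  \phi(i,j) = -RT \ln Propen(i,j).$$

A peptide $k$ is scored by the positional sum
$\phi_{tot}(k) = \sum_{j=1}^{6} \phi(r_j, j)$ under the amyloid-derived and
non-amyloid-derived matrices, and classified by the sign of
$\Delta\phi(k) = \phi_{tot}^{amy}(k) - \phi_{tot}^{non}(k)$: negative
predicts fibril formation; zero resolves to non-amyloid, reading the
decision rule's "otherwise" strictly.

The model is strictly position-additive: there are no residue-pair terms,
which is also why the synthetic generator (below) samples positions
independently.

## Parameters that matter

* **`rt` (kcal/mol, default 0.6).** The thermal constant $RT$ is not part
  of the published matrices' description; 0.6 kcal/mol is the standard
  value near 300 K and is the unique round value that makes the published
  preference thresholds consistent with the published energies: a
  propensity of 1.2 maps to $-0.6\ln 1.2 = -0.109$ kcal/mol, and the
  bundled amyloid matrix's borderline preferred entry at position 6
  (Tyr, $-0.112$) clears that bound while a non-listed entry at position 1
  (Phe, $-0.060$) does not. `rt` is configurable everywhere it enters.
* **Preference thresholds** (`preferred_min = 1.2`, `avoided_max = 0.8`,
  dimensionless propensities). A residue observed with propensity at or
  above 1.2 is *preferred* at that position; at or below 0.8 (including
  unobserved residues) it is *avoided*. The published avoided lists are
  subsets of what the 0.8 rule generates — the listing criterion for
  avoided residues was evidently stricter but is not stated — so the
  package's tests assert the one-directional subset property only.
* **`pseudocount` (default 0).** The published matrices were derived from
  raw counts, so the default adds nothing; a positive value fills
  zero-count cells at the cost of no longer reproducing published-style
  matrices.
* **Binning.** Energy-differential histograms use 0.2 kcal/mol bins
  aligned so the cutoff (default $-0.2$ kcal/mol) is a bin edge, matching
  how the published distribution analysis quotes ranges; the cutoff
  comparison is $\le$ so an energy exactly at the edge is counted.
  Hydrophobicity histograms default to bin width 50 with origin 0; none of
  these choices is dictated by the data and all are arguments.

## Zero counts and unobserved cells

$\phi = -RT\ln Propen$ is undefined at propensity 0. Published matrices
print such cells as 0.000; the package stores them as exactly 0 with an
`observed = FALSE` flag so they are distinguishable from genuine
propensity-1 cells. On reading a matrix file, zero cells are flagged
unobserved — the convention cannot distinguish a true 0.000 energy, which
would require a count exactly matching the background, an essentially
measure-zero event at realistic sample sizes. Unobserved cells contribute
0 to peptide scores (equivalent to assuming background propensity for
residues never seen at a position).

## The synthetic generator and effective potentials

`sample_dataset()` inverts the construction: residue $i$ is drawn at
position $j$ with probability proportional to
$q(i)\exp(-\phi(i,j)/(RT\,\tau))$, where $q$ is the globular background and
$\tau$ a temperature factor ($\tau = 1$ reproduces the bias strength of
the input matrix; $\tau \to \infty$ collapses to background). Defaults
mirror the reference study conditions: 139 amyloid and 168 non-amyloid
peptides drawn from the bundled matrices at $\tau = 1$.

Because unobserved cells re-enter at background weight, each position
column is renormalized, so the distribution actually sampled corresponds
to the input potentials shifted by a per-position constant
$RT\ln Z_j$. `effective_potentials()` returns that exact Boltzmann
inversion of the sampling probabilities. Two consequences matter:

* **Optimality.** Scoring with effective potentials makes
  $\Delta\phi = -RT \cdot \mathrm{LLR}$ exactly, so the sign rule *is* the
  equal-prior log-likelihood-ratio classifier for generator data — an
  algebraic identity the tests verify call-by-call against an explicitly
  computed likelihood ratio. With the raw bundled matrices the calls
  differ by a peptide-independent offset
  $\sum_j RT \ln (Z^{amy}_j / Z^{non}_j)$, i.e. a shifted decision
  threshold, not a different ranking.
* **Recovery.** `recovery_experiment()` compares potentials re-derived
  from a synthetic sample against the effective generating potentials —
  the true parameters of the sampling law. The sampling error of a derived
  cell is approximately $RT/\sqrt{count}$, so cells with expected count
  below 50 are reported as high-variance rather than entering the
  mean-absolute-deviation summary.

What the generator does *not* emulate: the single-substitution homology
structure of the real compilations (real non-amyloid peptides are often
one residue away from an amyloid parent), label noise from
concentration- and time-dependent fibrillization experiments, and any
positional coupling. Passing tests on synthetic data therefore demonstrate
the correctness of the machinery and its statistical behaviour under the
stated model, not real-data performance.

## The ensemble benchmark

`cross_validate()` evaluates a bagged randomized-tree ensemble
(randomForest; defaults 100 trees, $\sqrt p$ features per split, terminal
nodes of size 1) on stratified k-fold splits with pooled confusion counts.
The default feature encoding is the maximal superset: the six positional
energies under each matrix plus three property totals (hydrophobicity,
isoelectric point, and the synthetic stand-in long-range energy scale).
Leaner encodings are provided: the twelve energies, the six per-position
differentials, and the single summed differential `delta_total` — the
sufficient statistic of the generative model, on which the Bayes rule is a
threshold at a fixed offset.

The package's optimality benchmark (in the test suite and acceptance
script) compares cross-validated ensemble accuracy at 500 peptides per
class, 10 folds, against the $\Delta\phi$ rule on the same data. It uses
the `delta_total` encoding with a larger, regularized ensemble (300 trees,
minimum node size 100): on redundant multi-feature encodings, axis-aligned
trees approximate the additive linear discriminant with an excess risk of
one to a few percentage points at this sample size, which measures tree
bias rather than harness correctness; on the sufficient statistic, the
regularized ensemble reduces to a smoothed threshold learner and recovers
the optimal rule to within sampling noise. Problem sizes throughout the
validation suite (10,000-peptide oracle comparisons, 5,000 peptides per
class for parameter recovery, 500 per class for cross-validation) were
chosen so every check is statistically meaningful at interactive run
times.

## Property scales

Per-residue scales live in a tab-separated registry
(`inst/extdata/property_scales.tsv`). The hydrophobicity scale (reversed-
phase retention-time coefficients) is bundled in full and is the only
scale used in worked examples and tests of numerical claims. Isoelectric
points are textbook values. The long-range non-bonded energy scale is a
*synthetic stand-in* — named `longrange_energy_synthetic` — with plausible
ordering but arbitrary units, because the published per-residue values
live in an external compilation; the remaining 49 property names ship as
placeholder rows for users to fill in. Class summaries report the sample
standard deviation ($n-1$), the conventional reading of a "mean ± sd"
table.

## Known limitations

* Discrimination with the bundled matrices is asymmetric by construction
  — the positive class is much better characterized than the negative one
  — so specificity on real data is expected to be substantially lower
  than sensitivity.
* The 20-letter alphabet is strict: ambiguity codes and lowercase are
  rejected, not remapped.
* Duplicate policy on loading is exact-sequence identity; no
  homology-aware redundancy reduction is provided.
* The window scanner reports every hexapeptide window independently; it
  does not merge overlapping windows into consolidated APR intervals.
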