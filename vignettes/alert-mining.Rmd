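---
title: "Mining structural alerts for nephrotoxicity: methods and design"
author: "nephroSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining structural alerts for nephrotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroSA)
```

# The problem and the model

Nephrotoxic drugs injure the kidney through mechanisms — tubular
necrosis, crystal obstruction, interstitial nephritis, oxidative stress —
that are hard to predict from whole-molecule models alone. A long-standing
complementary approach in computational toxicology is the *structural
alert* (SA): a substructure that occurs so much more frequently in toxic
than in non-toxic compounds that its presence alone is a usable warning.

`nephroSA` frames alert discovery as univariate feature selection over a
binary substructure-key fingerprint. Each compound is described by a
vector of 0/1 bits, one per SMARTS pattern in a key dictionary
(Klekota–Roth-style keys; the full dictionary has 4,860 patterns, and the
package bundles the 16-alert nephrotoxicity catalog it ships with). For a
bit $b$ carried by $N_b$ compounds of which $N_b^+$ are nephrotoxic, two
statistics are computed:

* **Positive rate** $\mathrm{PR}(b) = N_b^+ / N_b$ — the precision of the
  bit read as a one-rule toxicity predictor.
* **f-score** — the Fisher discrimination score of the bit as a binary
  feature,
  $$F(b) \;=\; \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
                    {s_+^2 + s_-^2},$$
  where $\bar x$, $\bar x^\pm$ are the bit's overall and class-conditional
  means and $s_\pm^2$ the unbiased within-class variances. A bit equally
  frequent in both classes scores 0; a bit present in one class only, with
  zero within-class variance, is a perfect separator and scores
  $+\infty$ (infinite scores sort above all finite ones).

A bit becomes an alert when it passes three inclusive filters
(`MiningConfig`):

| parameter | default | meaning |
|---|---|---|
| `min_support` | 6 | carriers counted over the *whole* set (both classes) |
| `f_min` | 0.005 | minimum f-score |
| `pr_min` | 0.75 | minimum positive rate |

The defaults are the operating point of the nephrotoxicity analysis this
package implements; on a set of a few hundred compounds they admit rare
but strongly class-pure fragments (a bit carried by 6 toxic and 0
non-toxic compounds in a 287/278 set has $F \approx 0.011$, comfortably
above `f_min`) while rejecting low-support mixed bits. Alerts with
$N_b^- = 0$ are additionally flagged *exclusive*.

Screening then applies the any-alert rule: a compound is predicted
nephrotoxic iff at least one selected alert bit is set, and the matched
bits are reported per compound, which is what makes the method preferable
to a black-box model when interpretability matters.

## Design choices that were genuinely open

* **The f-score formula.** "f-score" is used in the QSAR feature-selection
  literature both for the Fisher score above (Chen & Lin's definition)
  and for the F1 measure. We adopt the Fisher score as the default: its
  scale matches a 0.005 threshold for rare binary bits, whereas F1 of a
  rare bit is bounded near $2N_b^+/N^+$ and would make the threshold
  nearly vacuous. The F1 variant remains available
  (`MiningConfig(score_method = "f1")`).
* **Filter order.** Support, f-score and positive-rate filters are
  applied conjunctively; since all comparisons are inclusive the result
  is identical whether support is filtered before or after ranking.
* **Degenerate bits.** A bit carried by nobody has an undefined positive
  rate; it is reported as `NA` and can never be selected (it fails the
  support filter first). Zero within-class variance with positive mean
  separation yields $+\infty$, never a division error.

# Evaluation mathematics

Classifiers (including the alert screen read as a classifier) are
summarized from the 2×2 confusion matrix with nephrotoxic = positive:
total accuracy $Q$, sensitivity $SE$, specificity $SP$ (all percentages),
Matthews correlation, and the enrichment factor

$$EF \;=\; \frac{TN/(TN+FN)}{(TN+FP)/N},$$

i.e. the precision of *negative* predictions relative to the
negative-class prevalence. This negative-class orientation is unusual but
deliberate: it is the form under which the published external-validation
tables this package reproduces are internally consistent, which we verify
by reconstruction (below). Under it, the trivial all-negative predictor
scores exactly 1 for every class balance — a useful null reference. AUC
is the normalized Mann–Whitney statistic (midranks for ties), checked in
the tests against exhaustive pair counting.

Two auditing tools round out the module:

* `reconstructConfusion(se, sp, n_pos, n_neg)` recovers the integer
  confusion matrix behind printed SE/SP percentages (nearest integer,
  half-up). With validation class sizes 55/54, printed values at two
  decimals pin the counts down uniquely, so published Q/EF/MCC can be
  re-derived exactly — the package's strongest internal-consistency
  check.
* `consensusPredict` averages member models' scores; the mean-0.5 tie
  classifies positive, because a toxicology screen should err toward
  sensitivity.

# Compound standardization

Input structures are reduced to a single parent before fingerprinting:

1. canonicalize; 2. split into fragments; 3. keep the largest *organic*
(carbon-containing) fragment by heavy-atom count, ties broken by carbon
count, then by lexicographically smallest canonical SMILES; 4. neutralize
protonation states; 5. re-canonicalize. "Largest organic fragment" is a
rule this package fixes explicitly — mixture records rarely state which
component is the active one, and heavy-atom count with deterministic
tie-breaks makes the choice reproducible. Purely inorganic records (e.g.
`[Na+].[Cl-]`) are flagged as standardization errors rather than guessed
at. Duplicate detection runs on the standardized canonical SMILES from a
single toolkit (Open Babel), not on InChI, so one aromaticity/tautomer
model governs both matching and deduplication; stereoisomers whose
canonical forms differ are kept distinct because their toxicity labels
may differ. Labels are decoded strictly (0/1, "0"/"1", "nephrotoxic"/
"non-nephrotoxic") — anything else is an error, never a coercion.

SMARTS matching, and therefore every fingerprint bit, is presence-based
(at least one embedding) under Open Babel's aromaticity perception. The
bundled catalog SMARTS are used verbatim; a dictionary perceived under a
different toolkit (e.g. CDK) may disagree on individual bits for corner
cases, which is why the test suite pins the matcher against an
independent brute-force subgraph-embedding enumerator on a fixture set
where the expected answers are derivable by hand.

# Molecular properties and chemical space

Eight properties support the toxic/non-toxic class comparison: MW, polar
surface area, AlogP, an ESOL-style LogS estimate
($0.16 - 0.63\,\mathrm{logP} - 0.0062\,\mathrm{MW} +
0.066\,\mathrm{nRotB} - 0.74\,\mathrm{AP}$, AP = aromatic proportion),
hydrogen-bond acceptor and donor counts, rotatable bonds (non-ring single
bonds between non-terminal heavy atoms, bonds to amide nitrogens
excluded), and aromatic rings (5/6/7-membered SSSR rings). These are one
toolkit's renderings of the descriptor family, chosen for determinism and
openness; absolute values differ across descriptor engines, so
*class-difference directions and significance*, not absolute means, are
the comparable outputs.

Class comparison uses the two-sided Welch t-test by default (the pooled
Student form is a flag): with class sizes in the hundreds and no reason
to assume equal variances, Welch is the safer default. Significance is
declared at $p < 0.05$; degenerate inputs (no variance, tiny groups) are
flagged with the p-value omitted rather than fabricated.

The chemical-space projection standardizes descriptors (constant columns
dropped), performs PCA, and reports the first two component scores with
their shares of total variance. Component signs are fixed so each
component's largest-magnitude loading is positive — scores are then
reproducible across BLAS implementations and descriptor orderings.

# The synthetic-data generator

The generator exists so that mining, screening and evaluation are
testable without the study's compound set, and its defaults *are* the
study conditions: 287 nephrotoxic / 278 non-nephrotoxic compounds, 4,860
fingerprint bits, 87 planted alert bits, and a background in which every
other bit is set independently with probability 0.05 — a rate typical of
sparse substructure-key fingerprints on drug-like molecules. Planted
supports are drawn uniformly from 6–40 (rare-to-moderate fragments, the
regime alert mining targets) and positive-rate targets uniformly from
[0.75, 1].

Two properties make the generator a test instrument rather than a
simulation:

* **Exact construction.** A planted bit with support $s$ and target rate
  $p$ is set in exactly $\mathrm{round}(sp)$ toxic and
  $s - \mathrm{round}(sp)$ non-toxic compounds, carriers drawn without
  replacement — realized counts match the specification by construction.
  One consequence is honest: for supports $s \equiv 3 \pmod 4$ with $p$
  just above 0.75, rounding can land the realized rate below the 0.75
  threshold (probability $1/s$ within the target band), so a small
  fraction of planted bits is genuinely unminable at the inclusive
  threshold; recovery experiments therefore bound recovery from below
  rather than asserting 100%.
* **Single seeded stream.** All sampling draws from one generator seeded
  once, in documented order (planted parameters, background, carriers),
  so equal seeds give bit-identical matrices and the caller's RNG state
  is untouched.

A second generator emits real SMILES: toxic compounds are alkyl-extended
exemplars of the bundled alert substructures, non-toxic compounds come
from a pool of alkyl/ether/amine scaffolds verified free of every bundled
pattern (violations retried, then an error). All vocabulary entries are
pairwise distinct after standardization, so deduplication is a no-op on
generated sets. By construction the classes are perfectly separable by
the planted alerts — so end-to-end tests can assert exact recovery and
100% screen accuracy. That is deliberately *unlike* real data, where
alerts are impure and overlapping; passing these tests demonstrates
correctness of the machinery, not expected field performance. What the
synthetic sets do not emulate: realistic property distributions,
correlated bits, label noise, or drug-likeness of the molecules.

## Problem sizes used in the shipped tests

Unit tests run on sets of 6–64 synthetic compounds and matrices up to a
few hundred bits; the parameter-recovery experiment runs 20 seeds at the
full study scale (565 × 4,860). The embedding-oracle cross-check uses 20
molecules of ≤ 15 heavy atoms against all 16 bundled patterns, a size at
which exhaustive enumeration is instantaneous and independently
verifiable.

# Numerical conventions

* Percentages are reported at two decimals in formatted output; full
  precision is kept internally.
* Nearest-integer reconstruction rounds half up (`floor(x + 0.5)`), not
  half-even, matching how printed percentages are produced from counts.
* Undefined metrics (zero denominators) are `NA` with a warning — except
  MCC, which follows the common convention of 0-with-warning when a
  marginal is zero.
* Tanimoto similarity defines 0/0 (two empty fingerprints) as 0.
* JSON serialization has no `Inf` literal; infinite f-scores round-trip
  through `null` and are restored on read.

# Known limitations

* Alert mining scores bits independently: co-occurring substructures and
  their spatial arrangement are invisible to it, and a compound carrying
  two alerts is not "more positive" than one carrying one.
* Cross-toolkit bit-for-bit agreement with CDK-derived substructure keys
  is not guaranteed and not claimed; the bundled catalog is matched under
  Open Babel's aromaticity model.
* LogS is an estimate fitted for neutral organics; charged or very large
  molecules fall outside its calibration.
* The pipeline evaluates prediction files produced elsewhere; it does not
  train QSAR models.
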