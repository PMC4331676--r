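---
title: "Distance transformation of PSSM profiles for DNA-binding protein identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance transformation of PSSM profiles for DNA-binding protein identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmdt)
```

## The problem and the model

DNA-binding proteins — transcription factors, histones, repair enzymes —
must be told apart from the rest of the proteome using sequence alone when
no structure is available. The signal this package exploits is
evolutionary: a PSI-BLAST position-specific scoring matrix (PSSM) records,
for every position $i$ of a protein of length $L$ and every amino acid
$j$, a log-odds score $S_{i,j}$ of observing $j$ at $i$. Positive scores
mark residues conserved beyond chance, and conserved arginines and other
positively charged residues are a hallmark of DNA contact surfaces.

Profiles of different proteins have different lengths, but a classifier
needs fixed-length inputs. The distance transformation solves this by
summarising the profile as lagged score co-occurrences. For an ordered
amino-acid pair $(a_1, a_2)$ and a lag $lg$:

$$\mathrm{DT}(a_1, a_2, lg) \;=\;
  \frac{1}{L - lg} \sum_{j=1}^{L-lg} S_{j,a_1}\, S_{j+lg,a_2}.$$

Descriptors with $a_1 = a_2$ form the *same-pair* block (SDT, $20\,LG$
values for a maximum lag $LG$); ordered pairs with $a_1 \ne a_2$ form the
*different-pair* block (DDT, $380\,LG$ values); their concatenation (SDT
first) is the full encoding with $400\,LG$ coordinates — 2000 at the
working default $LG = 5$. Each coordinate approximates how often its two
amino acids co-occur, evolutionarily, at that separation along the chain.

One indexing convention deserves emphasis because a silent transposition
yields wrong features: throughout this package the score matrix is indexed
`S[position, amino acid]`, the columns fixed in PSI-BLAST header order
(`A R N D C Q E G H I L K M F P S T W Y V`), and the sums above run over
*positions*. Raw integer log-odds scores are used as printed by PSI-BLAST;
no sigmoid, z-score or other normalisation is applied anywhere in the
encoders, and scores are stored as reals so synthetic profiles may be
real-valued.

The encoded vectors feed a soft-margin support vector machine with the
radial-basis-function kernel
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$, solved by LIBSVM. The
decision function is $f(x) = \sum_i \alpha_i y_i K(s_i, x) + b$, with the
label taken from the sign of $f$ and the $f = 0$ tie assigned to the
positive class.

## Tunable parameters

* **`LG` (maximum lag, default 5).** Dimensionless; controls both the
  longest residue separation captured and the feature-space size
  ($400\,LG$). Accuracy typically rises until `LG` covers the informative
  lags, then dips as further lags add noise dimensions; `lg_sweep()`
  reproduces that curve on any dataset.
* **`C` (penalty) and `gamma` (kernel width).** Selected by
  `grid_search()`: stratified 5-fold cross-validation over exponential
  grids, maximising mean accuracy with ties broken toward the smaller `C`
  then the smaller `gamma` (the weaker-regularisation-last convention
  keeps the selection deterministic). The package ships the conventional
  LIBSVM grids ($C \in 2^{-5}, 2^{-3}, \dots, 2^{15}$;
  $\gamma \in 2^{-15}, \dots, 2^{3}$) as `default_grids()`; the examples
  and tests pass compact sub-grids spanning the same decades, which is a
  deliberate problem-size choice documented below.
* **`scale_features` (default `FALSE`).** Raw lagged products have a wide
  dynamic range; a min–max scaler fitted on the training data only is
  available, but the default pipeline runs on raw features and lets
  `gamma` absorb the scale, which is also the behaviour assumed by the
  discriminant read-out below.

Hyperparameters are chosen **once** on the full training set and then held
fixed across jackknife rounds. That sequencing mirrors the original
protocol of this method; it is mildly optimistic (the held-out sample
participated in tuning), which the documentation flags rather than hides.
Per-fold re-tuning can be had by calling `grid_search()` inside any
resampling loop. In `lg_sweep()` the pair `(C, gamma)` *is* re-tuned per
`LG`, since each `LG` changes the dimensionality and reusing a tuning
across spaces would be ill-defined.

## Evaluation

Confusion counts yield SN, SP, ACC and the Matthews correlation
coefficient, with the standard $0/0 \to 0$ convention for MCC so that
label-independent random prediction is centred at zero even on degenerate
draws. The ROC curve is built by sweeping the decision threshold over the
distinct decision values, and the AUC is the Mann–Whitney statistic with
ties credited $0.5$ — identical to the trapezoidal area under the swept
curve. Under the jackknife, the single ROC is computed from the held-out
decision values pooled across all $n$ rounds. Percentages print to two
decimals.

## Discriminant-weight feature analysis

Which descriptors drive the decision? With the per-sample training weights
$A = (\alpha_1 y_1, \dots, \alpha_N y_N)$ (zero for non-support samples)
and the training feature matrix $M$, the feature-space read-out is

$$W = A^{\mathsf T} M, \qquad W_k = \sum_i \alpha_i y_i\, M_{ik}.$$

For an RBF model this is a first-order surrogate — the exact gradient of
the decision function is not linear in the features — but it is the
conventional read-out for kernel models and is linear in $A$. The weight
of an ordered amino-acid pair is the quadratic sum of its positively
weighted descriptors across lags (positive weights load on the
DNA-binding class; negative ones are deliberately excluded), giving a
$20 \times 20$ matrix whose entries partition the positive-part quadratic
mass of $W$. `per_lag_weights()` exposes the signed per-lag coordinates of
any pair, and `locate_descriptor_occurrences()` maps a high-ranking
descriptor back to literal residue-pair matches $(j, j+lg)$ in a sequence
(1-based, matching PSSM row numbering). Occurrence counting is literal
residue matching rather than any score-threshold rule; both "best lag
only" and "all lags" summaries can be assembled from the returned tables.

## The synthetic-data generator

Real benchmark profiles require a PSI-BLAST search of a large protein
database, so the package ships a generator that emulates the *structure*
of that data while staying fully seeded and offline:

* background scores are `round(N(0, 2))` — integer log-odds in roughly
  $[-6, 6]$, the range typical of real profiles; residues are uniform over
  the 20 amino acids;
* positives additionally receive a planted signal: for each planted triple
  `(aa1, aa2, lg)`, a `density` fraction of eligible start positions $j$
  gets `+effect_size` added to column `aa1` at $j$ and column `aa2` at
  $j + lg$, with the residue letters at those positions set coherently, so
  profile-based encoders and the sequence-based occurrence locator see the
  same signal.

The defaults define the package's study conditions and were fixed once:
30 positives and 30 negatives (n = 60), lengths 60–100 (above the
50-residue curation floor used for real data), planted pairs (R,R) at lag
4 and (A,R) at lag 5 — arginine-centred pairings of the kind that
distinguish DNA-binding proteins — at `effect_size = 5` (2.5 background
standard deviations, a deliberately strong plant) and `density = 0.25`.
The lag-sweep validation instead plants a single pair at lag 3 with
`effect_size = 2`, a moderate signal chosen so that the lag structure,
not the marginal score shift, carries most of the information.

What the generator does *not* emulate: alignment pseudocounts, per-column
information content, residue-composition biases of real proteomes, and
sequence redundancy structure. Passing tests on synthetic data therefore
demonstrate the correctness of the pipeline and the recoverability of a
planted lag/pair signal — not the headline accuracy achievable on real
benchmark profiles, which depends on the profile database and era.

## Numerical choices and degenerate inputs

* Encoders require $L > LG$; the divisor $L - lg$ would otherwise be
  non-positive. This is a hard error, not zero-padding.
* Sequences containing ambiguity codes (`X` and friends) are rejected at
  parse time rather than imputed, keeping every encoding well-defined.
* The ASCII PSSM parser keeps the first 20 (log-odds) columns, reorders
  scrambled column labels into the canonical order, and verifies that
  position indices are consecutive from 1.
* LIBSVM's termination tolerance is exposed (`tolerance`, default `1e-3`);
  the dual solution satisfies the box constraint
  $|\alpha_i y_i| \le C$ and, at tightened tolerance, matches an
  independent quadratic-programming solve of the dual to $10^{-6}$ on
  small instances (verified in the test suite against a primal-dual
  interior-point solver).
* All stochastic steps — fold assignment, the generator, Monte-Carlo
  checks — consume explicit integer seeds, and reruns are byte-identical
  at the level of serialized reports.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run entirely on synthetic
data: encoder/oracle cross-checks on 200 random profiles of length at most
30; SVM/QP agreement at $n \le 20$; jackknife and grid search at the
n = 60 study size with compact grids ($C \in 2^{-1 \dots 7}$,
$\gamma \in 2^{-15 \dots -5}$, steps of $2^2$); pair-recovery over 20
seeded replicates of n = 30; a three-point lag sweep; and 10,000
Monte-Carlo trials for the random-prediction MCC. These sizes keep the
whole validation in minutes on one core while leaving every contract
exercised at full fidelity.

## Known limitations

* Real-data benchmark figures are not reproducible without the original
  profile database; the package validates mechanism, not headline numbers.
* The discriminant read-out is a linear surrogate of a nonlinear model;
  ranks are meaningful, magnitudes are not calibrated.
* The four comparison encoders (`avepscore20`, `avepscore400`,
  `pscore100`, `acc_transform`) are frozen to one precise reading each —
  stated in their documentation — because their originating descriptions
  are one-line summaries; other readings exist (percentile grids,
  correlation normalisation) and would change their outputs.
* `run_psiblast()` requires an external `psiblast` executable and a
  formatted database; when a query has no hits there is no principled
  single-sequence fallback profile, so the operation errors rather than
  inventing one.

## A worked micro-example

```{r example, eval = FALSE}
sim <- generate_dataset(seed = 11)                      # n = 60 study size
enc <- encode_profiles(sim$profiles, "dt", LG = 5, labels = sim$labels)
gs  <- grid_search(enc, C_grid = 2^seq(-1, 7, 2),
                   gamma_grid = 2^seq(-15, -5, 2), folds = 5, seed = 11)
jk  <- jackknife(enc, C = gs$C, gamma = gs$gamma)
glance(jk)
model <- svm_train(enc, C = gs$C, gamma = gs$gamma)
discriminant_report(model, enc)$ranked_pairs[1:4]
```

On this seed the jackknife reaches 95% accuracy (MCC 0.905, AUC 1.00) and
the two planted pairs rank first and second — the end-to-end behaviour the
acceptance suite asserts.
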