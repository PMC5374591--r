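---
title: "Segment-conditioned high-order CRFs for residue burial states"
author: "burialCRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-conditioned high-order CRFs for residue burial states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burialCRF)
```

## The problem and the model

A protein residue is *buried* when its relative solvent accessibility
(RSA) — absolute accessible surface area divided by the residue type's
maximum ASA — falls below an exposure threshold of 0.25; otherwise it is
*exposed*. Buried residues form the hydrophobic core; exposed ones carry
most functional interactions. Burial states of nearby residues are
strongly correlated, and the correlation has a geometric period set by
the local secondary structure: on an α-helix, residues 3–4 positions
apart face the same side of the helix and tend to share a burial state;
on a β-strand the period is 2 (alternating side chains); on coils only
adjacent residues show appreciable correlation.

The model is a conditional random field over the binary label sequence
$Y = Y_1 \dots Y_L$ given per-residue features $X$, whose potential at
each position is selected by the secondary-structure segment containing
it. For a segmentation into segments $e_1, \dots, e_n$ (types H/E/C,
maximal runs of the 3-state secondary structure),

$$p(Y \mid X) \;=\; \frac{1}{Z(X)} \prod_{j=1}^{n} \exp\!\Big(
  \sum_{i \in e_j} \phi_{T(e_j)}(\cdot, i, X) \Big),$$

with per-position log-potentials

* coil: $\phi_C = \theta^\top f^0(Y_i, i, X) + \lambda^\top f^1(Y_{i-1}, Y_i, i, X)$,
* strand: $\phi_E = \phi_C + \mu^\top f^2(Y_{i-2}, Y_i, i, X)$,
* helix: $\phi_H = \phi_C + \gamma^\top f^3(Y_{i-3}, Y_i, i, X) + \tau^\top f^4(Y_{i-4}, Y_i, i, X)$

(there is deliberately no separation-2 term on helices). $f^0$ are
singlet features conjoined with the label; $f^1 \dots f^4$ are doublet
terms: label-pair indicators at the given separation conjoined with a
bias and, for orders 2–4, with the three profile-derived doublet
observations (mutual information, cosine similarity, contact-map score)
between the two positions. $\Lambda = (\theta, \lambda, \mu, \gamma,
\tau)$ is the weight vector, tied across positions and segments of the
same type.

### Term coverage and segment boundaries

Two structural decisions make the model well defined for every
segmentation, including length-1 segments:

1. **Every position contributes its singlet term exactly once.** Within
   a segment, each doublet order applies from the first position at
   which both of its label endpoints lie inside the segment: position
   $s{+}1$ of any segment gets the order-1 term, $s{+}2$ of a strand the
   order-2 term, $s{+}3$ / $s{+}4$ of a helix the order-3/4 terms. For
   long segments this reduces to products that start at $s{+}1$,
   $s{+}2$, and $s{+}4$ respectively; for short segments only the orders
   that fit are applied, with no error.
2. **Doublet terms never span two segments.** A consequence is that the
   distribution factorises over segments, so the partition function is
   a product of per-segment partition functions and all inference is
   exact — no approximation is ever needed at segment boundaries. (A
   variant that links segments could be added, but the factorised model
   is the one implemented and tested.)

## Exact inference

Within a segment the model is a chain of order $k$ (4 in helices, 2 in
strands, 1 in coils). `forwardBackward()` runs forward–backward
recursions over trellis states that encode the last $\min(j, k)$
labels — at most $2^4 = 16$ states and 32 transitions per position,
audited by `trellisStateCounts()`. All computation is in natural-log
space with log-sum-exp; probability-space products would underflow for
chains of realistic length. The forward and backward passes compute the
log-partition independently and must agree to $10^{-9}$, a cheap
internal consistency check that is also asserted in the tests.

Per-position marginals $p(Y_i = y \mid X)$ come from transition
marginals of the same trellis; `decodeLabels()` takes the per-position
argmax (exact ties go to buried, for determinism). The normative
definition of the marginals is brute-force enumeration over all $2^L$
labelings (`bruteForceReference()`, capped at $L \le 20$); the dynamic
program is required by the test suite to match enumeration to $10^{-9}$
across hundreds of randomized instances covering every segment-type mix,
rather than transcribing any particular closed-form marginal expression.
Joint (Viterbi) decoding is intentionally not part of the surface: the
decoder maximizes per-position marginals.

## Training

`fitBurialCRF()` maximizes the conditional log-likelihood
$\sum_m [\mathrm{score}(Y^m) - \log Z(X^m)]$ minus an L2 penalty
(default strength 1.0; the penalty is an addition of this
implementation, needed for identifiability — e.g. a constant shift of
$\theta$ across both labels is a gauge transformation that leaves
$p(Y\mid X)$ unchanged). The gradient is empirical minus expected
feature counts; expectations for the order-3/4 helix terms come from the
order-4 trellis transition marginals directly, with no approximation.
Analytic gradients are verified against central finite differences at
relative error $10^{-5}$ per coordinate on every weight block.

The default optimizer is full-batch gradient ascent with a backtracking
line search (step halved until the objective does not decrease, doubled
after every accepted step), which makes the recorded trace monotone. A
quasi-Newton mode (`optimizer = "lbfgs"`) is available and is what the
longer benchmark fits use. With L2 > 0 the objective is strictly
concave, so the optimum is independent of initialization; weights start
at zero. Real-valued singlet columns are z-scored with training-set
statistics that are stored in the model archive and re-applied at
prediction time; constant columns (e.g. the bias) are left untouched.

## Features

For real proteins the feature engine assembles, per residue: a bias;
residue-type one-hot (21 including X); terminal flags; the 20 profile
frequency columns of a PSI-BLAST ASCII PSSM (`readPSSM()`, with a
one-hot pseudo-profile fallback when no profile exists); sequence
conservation (relative entropy of the profile column against a
background, Robinson–Robinson by default); predicted secondary-structure
probabilities; contact number (residues within 8 Å at sequence
separation ≥ 5, `contactNumber()`); and any precomputed per-residue
columns (disorder or binding-site probabilities, physicochemical
tendencies, secondary-structure end tendencies, I-site scores, contact
potentials) read from TSV — these come from external predictors and are
never computed internally. The column registry is config-driven and the
total width is asserted from the registry, because the full published
layout of the singlet set is not itemized anywhere; the registry makes
the default explicit and extensible instead of hardcoding a count.

Doublet observations at separations 2/3/4 are mutual information, cosine
similarity and a contact-map score between profile columns. Columns of
one profile are marginals, so their outer-product joint has MI exactly
0; a pair-count joint can be supplied where alignment columns are
available. The contact-map score is accepted as a precomputed per-pair
matrix rather than re-derived from an uncited formula.

## The synthetic generator

The generator exists so that every claim above is testable without any
external corpus. Its defaults are the study conditions used throughout
the tests: chains of 50–150 residues (mean 100, matching the common
"at least 50 residues" filter), alternating-type segments with geometric
lengths (helix mean 10, strand 5, coil 6 — typical of globular
proteins, and long enough for the order-4 helix terms to activate),
four label-informative singlet columns, four pure-noise columns, and
three doublet observation columns per separation. Four presets named
after the structural-composition classes (`alpha`, `beta`,
`alpha/beta`, `alpha+beta`) vary the type mix and coupling strengths;
the `alpha` and `beta` presets use strong (0.8) couplings at the
separations their geometry favors.

Generation is deliberately *joint*: labels are drawn first from the
coupling-only prior process on the sampled segmentation (by
forward-filtering backward-sampling on the same trellis as inference),
then features are drawn class-conditionally — singlet columns as unit
variance Gaussians at $\pm$ `effectSize`/2 around the label, doublet
columns at $\pm$ effect around agreement of the flanking label pair,
at exactly the positions where that order is active. Because the
variances are shared, Bayes' rule gives $p(Y \mid X)$ in closed form
and it is *exactly* the segment-conditioned CRF returned by
`generatingModel()`: class means become $\theta$, pair means become the
doublet observation weights, prior couplings become the pair biases,
and the quadratic mean terms cancel between labels by symmetry. The
default effect size 1 with four informative columns puts the Bayes
accuracy of the singlet channel near $\Phi(1) \approx 0.84$, the same
scale as per-residue accuracies reported for real burial-state
predictors.

What the generator does *not* emulate: evolutionary structure in
profiles (columns are conditionally Gaussian, not Dirichlet-like
frequency vectors), sequence–feature dependence (the amino-acid letters
are uniform and only matter through features), 3-D geometry, or errors
in the secondary-structure segmentation (the model is conditioned on
the true segmentation). Passing tests therefore certify the
*machinery* — exact inference, sampling, training, and the value of
high-order structure when it is present — not accuracy on real
proteins, which depends on feature quality and segmentation accuracy.

`sampleLabels()` is the standalone exact sampler given features; its
agreement with enumeration probabilities (total variation < 0.02 over
$10^5$ draws) is the keystone test that certifies the sampler and the
inference engine against each other. The total-variation check is run
at $L = 6$: the plug-in TV estimate of a *perfect* sampler has expected
sampling error of order $\sqrt{2\cdot 2^L/(\pi N)}$, which at
$N = 10^5$ only leaves headroom below the 0.02 bound for $L \lesssim 6$.

## Numerical choices and degenerate inputs

* RSA exactly at the 0.25 threshold is **exposed** (the threshold is
  read as minimum exposure); the boundary is asserted in tests and the
  threshold is an argument.
* The maximum-ASA table is shipped as a data file (Tien et al. 2013
  theoretical values) and is replaceable by any named vector; it is
  never hardcoded in logic.
* Marginal ties decode to buried; chains with DSSP breaks are split at
  the break for prediction and conventionally excluded from training.
* Length-1 segments, all-helix/all-strand/all-coil chains, and
  single-residue proteins are all legal inputs and covered by tests.
* Model archives are JSON with 17 significant digits, which round-trips
  IEEE doubles bit-exactly.

## Problem sizes used in the checks

The randomized suites use chain lengths 1–12 against enumeration (500
instances), 50 finite-difference instances, $10^5$ sampler draws, and
benchmark fits of 25–200 proteins of mean length 100 with a 40-protein
held-out set; the model-comparison experiment uses five independent
seeds with 40 training and 30 test proteins each. These sizes give the
statistical checks comfortable power while keeping the whole suite
quick on a single CPU.

## Limitations

The implementation covers two burial states only (no three-state
accessibility alphabets), conditions on a given segmentation rather
than marginalizing over secondary-structure uncertainty, and keeps
doublet terms within segments (the factorised reading). Baselines
included for comparison are per-residue logistic regression and the
first-order chain CRF (this engine with every chain treated as one coil
segment); neural sequence models are out of scope.
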