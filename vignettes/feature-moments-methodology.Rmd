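---
title: "Position-relative incidence features and moment descriptors for DNA-binding protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-relative incidence features and moment descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnabindR)
```

## The problem and the model

Whether a protein binds DNA is largely determined by its sequence, but
the signal is distributed: composition (DNA-binding domains are enriched
in basic residues), absolute residue position, and relative residue
order all carry information. `dnabindR` encodes a sequence of length $k$
into a 120-dimensional descriptor built from three complementary views:

1. **Composition.** The frequency vector $\tau_1,\dots,\tau_{20}$ of
   residue counts over the fixed alphabet (alphabetical one-letter
   order). Conservation: $\sum_i \tau_i = k$.
2. **Absolute position.** The accumulative absolute position incidence
   vector $\mu_i = \sum_{p:\,s_p = i} p$ with 1-based positions, and its
   reverse-sequence counterpart $\eta_i$. Because reversal maps position
   $p$ to $k+1-p$, the exact identity $\eta_i = (k+1)\tau_i - \mu_i$
   holds, and both vectors sum to $k(k+1)/2$.
3. **Relative order.** The $20\times 20$ position-relative incidence
   matrix (PRIM) with entries
   $$Y_{i\to j} \;=\; \sum_{\substack{p:\, s_p = j \\ p > f_i}} (p - f_i),$$
   where $f_i$ is the position of the *first* occurrence of type $i$;
   plus the same matrix computed on the reversed sequence (RPRIM).

Each incidence matrix is condensed into 30 statistical moments of order
$\le 3$: raw moments $M_{xy}=\sum_i\sum_j i^x j^y Y_{ij}$, central
moments $U_{xy}$ about the centroid $(M_{10}/M_{00},\,M_{01}/M_{00})$,
and discrete Hahn moments $H_{ij}$, i.e. projections onto the
weighted-orthonormal discrete Hahn polynomial basis. The fused layout is
PRIM moments (30), RPRIM moments (30), AAPIV (20), RAAPIV (20), FV (20)
— 120 values, versioned as `120-v1`.

## Conventions that had to be fixed

Several choices are under-determined by the narrative description of
this feature family; the package fixes them once and documents them, so
every downstream number is deterministic:

- **Alphabet order** is alphabetical by one-letter code. Every vector
  slot and matrix index depends on it.
- **Positions are 1-based**, so the first residue contributes 1 to the
  position sums rather than being invisible.
- **PRIM reference point** is the *first* occurrence of the row type
  $i$; offsets of *every* occurrence of the column type $j$ after it are
  summed. This is computable in one pass, yields non-negative integers,
  and reduces to intuitive values on toy inputs (`prim("ACA")` has
  exactly $Y_{A\to C}=1$, $Y_{A\to A}=2$, $Y_{C\to A}=1$). Rows of
  absent residue types are all zero — no sentinel values — which keeps
  the moments finite.
- **Moment grid coordinates are 0-based** ($i,j = 0..19$), matching the
  support of the discrete Hahn polynomials.
- The square row-major reshaping of a sequence
  (`square_seq_matrix()`, side $\lceil\sqrt{k}\rceil$ with pad markers)
  is exposed as a utility, but its moments do **not** enter the fused
  vector: the 120-value accounting (30 + 30 + 20 + 20 + 20) covers only
  the structures listed above.

## The Hahn basis

Classical Hahn polynomials $Q_n(x;a,b,N-1)$ are evaluated by the
terminating hypergeometric sum
$Q_n(x) = {}_3F_2(-n,\, n+a+b+1,\, -x;\; a+1,\, -(N-1);\; 1)$
with a term-by-term recurrence (at most $n\le 3$ terms in production
use, so no cancellation issues), then scaled by
$\sqrt{\rho(x)/d_n^2}$ with the standard weight and squared norm, both
computed in log-gamma space so the construction is stable at the
$N = 20$ support of the incidence matrices. Defaults $a=b=0$ (the
discrete Chebyshev family) are used because nothing in the feature
definition selects other values; both parameters are exposed.

Correctness is established structurally rather than from any printed
formula: the basis must be orthonormal
($\max |\langle \tilde h_m, \tilde h_n\rangle - \delta_{mn}| < 10^{-8}$
at $N=20$), must agree with an independent Gram–Schmidt construction
(orthonormal polynomial sequences are unique up to sign, fixed positive
at $x=0$), and the full-order basis must reconstruct a random matrix
from its coefficients to $10^{-6}$.

**Degenerate inputs.** An all-zero matrix has no centroid; the moment
set is defined as 30 zeros and a warning is raised instead of dividing
by $M_{00}=0$. A single-residue sequence yields an all-zero PRIM (no
position follows the first occurrence), which exercises exactly this
path.

## Classifiers

- **Random forest** (`randomForest`): 100 trees, per-node subset
  $\lfloor\sqrt{120}\rfloor = 10$, unlimited depth — the standard
  defaults for this family of predictors. Scale-invariant, hence no
  feature scaling.
- **SVM** (`e1071`): RBF kernel, $C=1$, $\gamma = 1/(120\cdot
  \mathrm{var})$; linear and polynomial kernels selectable. Features are
  z-scored with a scaler fitted on training rows only and stored in the
  model, because the margin is scale-sensitive and the raw moment
  magnitudes span orders of magnitude.
- **Neural network** (own implementation): one hidden layer of 20
  logistic units plus biases (without biases the all-zero-input output
  is pinned at 0.5, crippling learning), mean-squared-error objective,
  full-batch gradient descent, weights initialized uniform$(-0.5, 0.5)$
  from the seed. The learning rate adapts per epoch: if the training
  error rose relative to the last accepted epoch, that epoch's update is
  discarded and $\gamma \leftarrow 0.7\,\gamma$; otherwise it is kept
  and $\gamma \leftarrow 1.05\,\gamma$. The factors are conventional
  values for this accept/revert scheme; the mechanism, not the
  constants, is what matters, and both are configurable. A direct
  consequence — the accepted-error trace is non-increasing — is tested
  on every run.

No class reweighting is applied anywhere: the reference benchmark for
this problem is roughly 4:1 negative:positive, and unweighted training
reproduces the expected high-sensitivity / lower-specificity pattern.

## Validation protocols and metrics

All four protocols pool test predictions into a single confusion matrix
whose totals equal the number of evaluated sequences (per-fold metric
averaging is deliberately not the default: a single pooled matrix is
what published confusion tables correspond to). Splits are stratified by
class; per-fold model seeds are `seed + fold`, so a report is a pure
function of `(dataset, protocol, seed)`. k-fold with $k = n$ collapses
to identity fold assignment — fold $i$ tests row $i$ — making the
jackknife *literally* the same computation, a property asserted exactly
in the tests rather than approximately.

Metrics come in two algebraically equivalent formulations — the
confusion-cell one and the alias one based on $N^+$ (true binders),
$N^-$ (true non-binders), $N^+_-$ (missed binders), $N^-_+$ (false
binders):
$$\mathrm{MCC} = \frac{1 - \left(N^+_-/N^+ + N^-_+/N^-\right)}
{\sqrt{\left(1 + \frac{N^-_+ - N^+_-}{N^+}\right)
       \left(1 + \frac{N^+_- - N^-_+}{N^-}\right)}}.$$
Their agreement to $10^{-12}$ over random tables is a standing test. A
metric with a vanishing denominator is reported `NA`, never silently 0:
the alias MCC divides by both class sizes and would otherwise fail
invisibly on single-class data. Cell products are computed in double
precision — at benchmark scale ($5.7\times 10^4$ sequences) the MCC
denominator overflows 32-bit integers.

The ROC is a threshold sweep over distinct scores with trapezoidal
area; it is cross-checked in the tests against both an exhaustive
pair-counting oracle and an established ROC package.

## The synthetic generator

`synthetic_spec()` + `generate_synthetic()` produce labeled datasets
with controllable signal so the entire pipeline is testable without any
external download. Lengths are uniform on a range (the simplest
controllable choice), residues i.i.d. from per-class composition
weights, and an optional fixed k-mer motif overwrites a window at a
uniform position in a configurable fraction of positives (overwriting
keeps lengths in range). The default class imbalance is 1:4
positive:negative, echoing curated DNA-binding benchmarks.

Three canonical settings are used throughout the tests:

- **Separable** (disjoint composition supports, $n = 400$, lengths
  30–80): composition alone separates the classes; pooled 10-fold RF
  accuracy must reach at least 0.90 (it reaches 1.0 in practice).
- **Null** (identical class compositions, 200 + 200): no learnable
  signal; pooled accuracy must stay within 0.05 of chance and MCC
  within 0.1.
- **Positional motif** (16-mer `(AC)×8` planted with probability 1 in
  positives of length 60, A/C background weight 0.10, negatives
  composition-compensated to the positives' expected post-planting
  marginal): the class signal lives in residue *order*. The full
  120-feature model must reach 0.75 pooled accuracy while a
  frequency-vector-only ablation stays at or below 0.60. This is the
  most delicate property in the suite: a planted fixed k-mer always
  perturbs the count *distribution* (it reduces the variance of its
  letters' counts even when means are matched), so the ablation bound
  has only a small margin; the construction above is the one we found
  where both bounds hold jointly.

What the generator does **not** emulate: real domain architecture,
evolutionary correlation between neighboring residues, realistic length
distributions, or any actual DNA-binding biochemistry. Passing the
recovery tests therefore demonstrates that the pipeline extracts the
kinds of signal it claims to (compositional and positional) — not that
it attains any particular accuracy on real proteomes.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized for quick, deterministic
desk-scale runs: 400-sequence datasets for recovery properties,
30-sequence datasets for the jackknife identity (25-tree forests), 100
random $6\times 6$ matrices for moment-oracle equivalence
($10^{-8}$), 500 random sequences for the conservation laws (exact
integer identities), 1000 random confusion tables for the formulation
identity ($10^{-12}$), orthonormality at $10^{-8}$. The published
benchmark itself (57k sequences) is external to the package; its
headline accuracies are recomputed from the published confusion
matrices, which is also what `scripts/acceptance.R` reports.

## Known limitations

- The first-occurrence PRIM convention is one of several defensible
  readings of "position-relative incidence"; it is versioned
  (`120-v1`) so descriptors from other conventions can never be mixed
  silently.
- Raw moment magnitudes grow with sequence length (no length
  normalization is applied, by design); scale-sensitive classifiers
  must use the provided z-scoring, which the SVM/ANN trainers do by
  default.
- The ANN is a reference implementation of the adaptive-rate mechanism,
  not a performance-tuned learner; with a non-convex objective the
  revert rule guarantees monotone accepted error but not convergence to
  a global optimum (the XOR test passes only for some seeds, as
  expected).
- `sanitize_sequence("...", "map")` rejects `X` (no compositional
  information); datasets rich in ambiguity codes should use the
  `"drop"` policy and review the rejection counts the loaders report.
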