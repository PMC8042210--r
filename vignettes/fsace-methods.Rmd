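---
title: "Feature selection by approximate conditional entropy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature selection by approximate conditional entropy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsace)
```

## The problem

Gene expression classification problems have tens to a few hundred
samples and thousands of attributes, almost all irrelevant to the class
labels. A filter feature-selection method must rank or select attributes
without training the downstream classifier. `fsace` implements a
granular-computing filter: it measures how much *knowledge uncertainty*
about the class labels remains once the samples have been granulated by
their pairwise similarity under a candidate attribute subset, and
greedily grows a subset until that uncertainty matches the full
attribute set's.

## The model

**Fuzzy relation.** For an attribute subset $B$ and kernel width
$\sigma > 0$, object similarity is the Laplacian kernel on the Euclidean
distance restricted to $B$:
$$r_{ij} = \exp\!\left(-\frac{\lVert x_i - x_j \rVert_B}{\sigma}\right) \in (0, 1].$$
Row $i$ of the relation matrix is a fuzzy set describing object $i$'s
similarity to every object. The Laplacian kernel is preferred to the
Gaussian for its sharper peak and heavier tail, which separate
near-duplicates from the bulk more decisively.

**Approximately-equal granulation.** Exact equality of fuzzy memberships
is useless on continuous data, so two relation rows are *approximately
equal at threshold $k$* when at every position their values fall in the
same of $k$ equal-width bins of $[0,1]$ (the last bin is closed:
$[(k-1)/k,\,1]$). This is an equivalence relation on rows, and the
induced classes $[x]_R$ — the *fuzzy information granules* — partition
the universe. `bins` ($k$) and `sigma` jointly set the granulation
coarseness.

**Approximate conditional entropy.** For the decision partition
$\{X_1,\dots,X_K\}$, each class has a rough-set approximation accuracy
$a(X_j) = |\underline{X_j}| / |\overline{X_j}|$, the ratio of the sizes
of its lower and upper approximations under the granulation. The score
blends the information view (conditional entropy over granules) with the
algebra view (boundary imprecision):
$$H_{ace}(D/B) = -\sum_{j=1}^{K} \log_2\!\big(2 - a(X_j)\big)
  \sum_{i=1}^{n} \frac{|[x_i] \cap X_j|}{n}
  \log_2 \frac{|[x_i] \cap X_j|}{|[x_i]|}.$$
The inner sum runs over *objects*, not distinct granules — that reading
is forced by the extremal configuration: a single universal granule with
all-singleton classes gives $H_{ace} = n \log_2 n$, and only the
per-object sum reproduces it. $H_{ace} = 0$ exactly when every granule
lies inside one decision class. All logarithms are base 2, including the
$\log_2(2 - a)$ damping weight, and $0 \log 0 := 0$.

**Greedy search (FSACE).** Attribute importances are entropy
differences: internal importance $IIA(c) = H_{ace}(D/(C - \{c\})) -
H_{ace}(D/C)$ (positive for *core* attributes), and external importance
$IEA(d, B) = H_{ace}(D/B) - H_{ace}(D/(B \cup \{d\}))$. The search
seeds $B$ with the core, then repeatedly adds the remaining attribute
with maximal IEA until $H_{ace}(D/B)$ matches $H_{ace}(D/C)$ within
`tol`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | — (swept) | Laplacian kernel width, in units of normalized attribute distance; smaller is finer granulation |
| `bins` | 4 | bin count $k$ of the approximately-equal relation; 4 is coarse enough to form non-singleton granules at moderate `sigma` while still separating clear structure |
| `tol` | 1e-10 | absolute entropy tolerance for "equal entropy"; exact equality is unreachable in floating point |
| `normalize` | TRUE | per-attribute min-max rescaling to $[0,1]$; kernel widths below 1 are only meaningful on normalized data |
| `max_features` | all | hard cap on the subset size |

Attributes are min-max normalized by default; constant attributes map to
all zeros rather than dividing by zero. Euclidean distances are *not*
rescaled by subset size — faithful to the kernel as printed — so the
width that granulates a 1-attribute subset coarsely is roughly
$\sqrt{|B|}$ times the width suited to a $|B|$-attribute subset. This is
why [choose_sigma()] sweeps a log-spaced grid `c(0.25, 0.5, 1, 2, 4)`
by default: on normalized data, single-attribute distances span $[0,1]$
and the bin boundaries of the granulation sit at $d = \sigma\ln(4/3)$,
$\sigma\ln 2$, $\sigma\ln 4$, so coarse single-attribute granules need
$\sigma \approx 2\!-\!4$, while multi-attribute subsets need widths
below 1. The width itself is chosen, per the usual protocol, as the one
whose selected subset cross-validates best.

## Design choices where the design was open

* **Bin count.** The approximately-equal relation only requires *some*
  $k \ge 2$ to exist; operationally it must be fixed. It is a user
  parameter with default 4, exposed on the CLI.
* **"For all" reading.** Row equivalence requires bin-identity at
  *every* position, consistent with the "for any $x$" form of the
  defining relation.
* **Empty subset.** $H_{ace}(D/\varnothing)$ is defined through the
  universal granulation (one granule covering all objects): with no
  attributes there is no discernibility. The greedy loop can start from
  an empty core, so this case is load-bearing.
* **Tie-breaking.** Argmax ties in the greedy step go to the lowest
  attribute index; the pipeline is then fully deterministic.
* **Termination guards.** The plain algorithm exits only on exact
  entropy equality, which binning can make unreachable (granules are not
  guaranteed to shrink when attributes are added, because bin membership
  of kernel values is not monotone in distance). The implementation adds
  three guarded stops — best IEA below `tol` once something is selected,
  `max_features` reached, all attributes taken — and reports which fired
  via `stop_reason`. Subset-monotonicity of $H_{ace}$ is *measured* by
  the test suite (violations logged), never assumed.
* **Degenerate tables.** A single-class table still selects exactly one
  attribute (the empty set is sent unconditionally into the addition
  step; all IEA are zero; the tie-break picks attribute 1), after which
  the entropies match and the run converges.
* **Backward pruning.** The forward pass can emit a proper superset of a
  reduct. An optional `prune = TRUE` pass removes attributes whose
  removal keeps the entropy matched; it is off by default to stay
  faithful to the printed control flow.
* **Caching.** Entropy values are memoized by the granulation signature
  within a run; results are identical with `use_cache = FALSE` (tested).

## What the synthetic generator emulates

`generate_table()` produces tables shaped like small expression panels:
tens of samples, 2–9 classes, a few informative attributes among many
standard-normal noise attributes. Informative attribute $t$ raises the
class mean by `effect` within-class standard deviations for all classes
above a threshold boundary $p = ((t-1) \bmod (K-1)) + 1$, so each
informative attribute resolves a *different* class boundary and the full
informative set is jointly necessary — a recovery test cannot be passed
by finding one strong marker. Columns are shuffled deterministically by
the seed so the lowest-index tie-break cannot favour ground truth.
Defaults: 60 samples, 3 balanced classes, 2 informative attributes at 6
standard deviations separation, 20 noise attributes.

The generator does **not** emulate heavy-tailed expression noise,
attribute correlation blocks, batch effects, or class-size imbalance
beyond what `class_proportions` states. A green recovery test therefore
establishes that the entropy score and greedy search work on
well-separated Gaussian class structure at desk scale — not that they
match any particular benchmark accuracy on real microarray data.

## Numerical choices and degenerate inputs

* Bin assignment is `floor(value * bins)` with value 1 in the last bin;
  values infinitesimally below a boundary land in the lower bin. No
  epsilon correction is applied — granulations near a boundary are
  sensitive to that boundary by construction, and papering over it with
  tolerances would make the partition depend on evaluation order.
* Entropy comparisons use the absolute tolerance `tol` (default 1e-10).
* Class terms with empty intersections contribute zero.
* The approximation-accuracy denominator is never zero for nonempty
  sets, since the upper approximation contains the set.

## The evaluation harness

Stratified $k$-fold cross-validation (folds dealt round-robin within
each class, seeded) with three classifiers: 3-nearest-neighbour
(`FNN`), a Gini-impurity CART-style tree, and an RBF-kernel
least-squares SVM — one-vs-rest kernel ridge solved in closed form,
standing in for a hinge-loss SVM since no QP solver is available in the
supported dependency set. Stratification is used because classes as
small as 2 samples occur in the data shapes being emulated. Folds
exceeding the smallest class size are an error, not a silent reshuffle.

## Known limitations

* The entropy rewards *fine* granulation wherever it occurs: a noise
  attribute whose kernel rows all discretize distinctly yields singleton
  granules and $H_{ace} = 0$, indistinguishable from genuinely
  discriminative structure. Width selection by cross-validated sweep is
  therefore not optional; at widths below ~1.5 on normalized data the
  greedy reliably prefers noise.
* Complexity is $O(n^2 |B|)$ per entropy evaluation and $O(m)$
  evaluations per greedy step; the core computation is $O(n^2 m^2)$ and
  can be skipped (`skip_core = TRUE`) on very wide tables.
* The selected subset is a superset of a reduct in general; only
  condition 1 of the reduct definition is guaranteed at convergence.
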