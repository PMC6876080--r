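---
title: "Identifying disease-related proteins with bagged logistic regression and gradient-descent refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying disease-related proteins with bagged logistic regression and gradient-descent refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrgd)
```

## The problem and the working hypothesis

Curated disease–protein associations are sparse: for most diseases only
a handful of related proteins are catalogued, and discovering new ones
by experiment is slow. `lrrgd` implements a guilt-by-association
strategy built on a single hypothesis: *similar diseases share related
proteins*. If a candidate protein is associated with several diseases
that are semantically close to the target disease, it is a plausible
target-disease protein even when no direct association is recorded.

The pipeline has three stages:

1. **Disease similarity.** Every candidate disease is scored against
   the target by five ontology-based measures; the five scores are
   summed into a combined similarity and thresholded to retain a
   candidate set.
2. **Feature extraction.** The retained diseases' associated proteins
   form a binary disease × protein matrix $X$; each disease's label $y$
   is its normalized combined similarity to the target.
3. **Ensemble regression.** Hundreds of small logistic-regression
   models, each on a random protein subset, regress $y$ on $X$. Each
   model then "asks" which of its proteins must be switched on for the
   predicted similarity of the target to itself to approach 1; proteins
   switched on often enough across the ensemble are reported as
   target-related.

## Disease similarity

### Information content and MICA

Let $c(t)$ be the number of distinct entities annotated at or below
term $t$ after propagating every annotation to all of the term's
ancestors (`is_a` and `part_of` links only). The information content is

$$\mathrm{IC}(t) = -\ln\frac{c(t)}{c(\text{root})},$$

so roots have IC 0 and IC is non-decreasing from root to leaf. The most
informative common ancestor (MICA) of two terms is the shared ancestor
with maximal IC; ties break on the lexicographically smallest term id so
results are deterministic, and when no shared ancestor carries positive
IC the common root is returned with IC 0. The natural logarithm is
used, the convention in the Resnik/Lin literature; terms with zero
propagated count carry no IC entry and behave as IC 0, which avoids
$-\ln 0$.

### The five measures

* **Resnik**: $4 \cdot \mathrm{IC}(\mathrm{MICA}(t_1,t_2)) /
  \mathrm{IC}_{\max}$. The raw MICA information content is rescaled to
  $[0,4]$ so that the combined score below is bounded by 8.
* **Lin**: $2\,\mathrm{IC}(\mathrm{MICA}) /
  (\mathrm{IC}(t_1)+\mathrm{IC}(t_2))$, 0 when the denominator is 0.
* **Wang**: each ancestor $t$ of a term $A$ receives a semantic
  contribution $S_A(t)$, 1 at $A$ itself and otherwise the maximum over
  child edges on paths down to $A$ of the child's contribution times a
  relation-specific decay (defaults 0.8 for `is_a`, 0.6 for `part_of`,
  the weights of Wang's original formulation). Similarity is the summed
  contributions over shared ancestors normalized by the two terms'
  total contributions.
* **PSB surrogate**: the published process-similarity-based measure is
  only cited, never specified, by the work this package follows; the
  package therefore ships a clearly labelled surrogate with the same
  signature and range: a best-match average over the two diseases'
  biological-process GO terms with pair score
  $\mathrm{IC}(\mathrm{MICA})/\mathrm{IC}_{\max}$ restricted to the BP
  namespace. A disease with no BP terms scores 0 with a warning.
* **SemFunSim surrogate**: likewise a documented stand-in: a best-match
  average over the two diseases' gene sets, scoring identical genes 1
  and other pairs by their weight in a gene functional-association
  network (0 when absent).

Resnik, Lin and Wang are term-pair measures; diseases are term *sets*.
They are lifted by the best-match average (BMA),

$$\mathrm{bma}(S_1,S_2) = \tfrac12\Big(
  \overline{\max_{b \in S_2} s(a,b)}^{\,a \in S_1} +
  \overline{\max_{a \in S_1} s(a,b)}^{\,b \in S_2}\Big),$$

the standard set aggregation in the semantic-similarity literature:
symmetric, bounded, and equal to the pair score on singletons. When a
disease-ontology DAG with an IC table is supplied the three measures
run over the diseases' own ontology terms (the default route);
otherwise they run over the GO-term profiles of the diseases' gene
sets.

### Combination, normalization, retention

The combined score is the plain sum of the five, bounded by
$1+1+1+1+4 = 8$, and the normalized similarity is $y =
\text{total}/8 \in [0,1]$. Self-similarity is *not* forced to 1: a
disease whose own ontology term is not maximally informative, or whose
BP term set is empty, legitimately scores below the maximum, and the
published reference table (`ad_similarity_reference()`) shows exactly
that for its self-comparison row (total 6.47 of 8).

Candidate diseases are retained when their total meets a threshold
(inclusive comparison; default 3.5). The threshold is a property of the
similarity distribution at hand — it should separate the handful of
genuinely related diseases from the indifferent mass. For the synthetic
fixture (below) the analogous cut is 1.5.

## Feature matrix

Associations are deduplicated pairs (disease, protein accession).
Diseases associated with fewer than `min_proteins` (default 1) or more
than `max_proteins` (default 2000) proteins are excluded — the cap
removes umbrella terms that subsume the target and would relate it to
thousands of proteins — as are explicitly listed ids. `X[d, p] = 1` iff
disease $d$ is associated with protein $p$; feature order is first-seen
order, frozen so ensembles are reproducible. The target disease is kept
as a training row with its own normalized self-similarity as label (a
configurable flag excludes it). The share of pooled associations whose
protein recurs for another disease (`redundancy_stats()`) quantifies
the cross-disease sharing the method exploits; curated tables at this
scale show roughly 40–55% redundancy.

## The ensemble

With a few dozen diseases and hundreds-to-thousands of proteins, a
single regression is hopelessly under-determined. Borrowing the random
forest convention, each of `n_rounds` (default 400) rounds draws
$\lfloor\sqrt{p}\rceil$ features without replacement (the pool is
restored between rounds), so each protein is selected
$n_\text{rounds}\sqrt{p}/p$ times in expectation — about 10 for 1608
proteins.

### Per-bag fit

Each bag fits a logistic regression of the fractional labels on the
bagged binary features by minimizing

$$J(\theta) = -\frac1m\sum_i\big[y_i\log h_\theta(x_i) +
  (1-y_i)\log(1-h_\theta(x_i))\big] +
  \frac{\lambda}{2m}\lVert\theta_{-0}\rVert^2,$$

with $h_\theta(x) = (1+e^{-\theta^\top x})^{-1}$. Cross-entropy is a
proper scoring rule for $y \in [0,1]$, so fractional similarity labels
need no binarization. The ridge term (default $\lambda = 1$) makes the
Hessian invertible when the bag is wider than the sample count; the
intercept is unpenalized. Newton steps are damped by step-halving until
the penalized loss does not increase, predicted probabilities are
clipped at $10^{-12}$ inside logs, and convergence is declared when the
step norm falls below `tol` (default $10^{-8}$, 50-iteration cap). A
singular Hessian at $\lambda = 0$ raises an error directing the user to
a positive ridge.

### Indicator refinement by projected gradient descent

The fitted model maps protein patterns to similarity. To turn it into
protein calls, the package minimizes

$$f(x) = (h_\theta(x) - 1)^2$$

over a *relaxed indicator vector* $x \in [0,1]^{|\text{bag}|}$: which
proteins must be present for the model to predict the target's
self-similarity of 1? Descent steps $x \leftarrow x - k\nabla f$
(default $k = 0.1$) are followed by projection of each coordinate onto
$[0,1]$; iteration stops when $|f_{n+1}-f_n| < \varepsilon$ or after
`max_iter` (default 10000) steps. The start is the *informed
initialization*: 1 for bag proteins in the known seed set, 0 elsewhere.
The final vector is binarized at 0.5, and the 1-entries are the bag's
called proteins.

The stopping tolerance deserves a note, because the refinement's
character depends on it. $f$ is monotone in $\theta^\top x$, so its
*unbounded-time* constrained optimum is degenerate: every coordinate
with a positive weight at 1 and every negative-weight coordinate at 0,
regardless of weight size or initialization (the package's property
tests verify exactly this limit). Run that far, the refinement would
reduce to reading off coefficient signs — the informed initialization
would be irrelevant, and tiny chance-correlated weights would be called
as confidently as strong ones. The default $\varepsilon = 10^{-3}$ is
therefore chosen on the scale of the loss itself, which lives in
$[0,1]$: iteration stops once a step improves the predicted-similarity
gap by less than 0.1% of its range. That keeps the refinement local to
the initialization, as intended — coordinates cross the 0.5 call
threshold roughly in order of weight magnitude before progress stalls —
while remaining far below any meaningful change in $f$. Users wanting
the saturated sign behaviour can pass a tighter `gd_tol`.

### Voting

Every bag protein gains one selection count; those binarized to 1 gain
one call count. Rounds whose Newton fit fails still count as selections
(with a warning) so call fractions stay honest. Proteins with calls at
or above `vote_threshold` (default 7, inclusive) are reported, and the
known-versus-novel split among them is summarized by
`known_fraction()`. Per-round RNG substreams are derived once from the
master seed, so a tally is a pure function of its inputs and the seed.

## The synthetic fixture generator

Real inputs are multi-gigabyte ontology and annotation releases; the
generator builds the same statistical structure at desk scale so every
stage is testable offline.

* **Disease ontology**: a root-to-leaf chain with the target at the
  bottom; the rank-$r$ disease sits $r$ steps above it, so ontology
  depth and designed closeness agree and the MICA-based measures grade
  smoothly.
* **Associations**: the target's row is exactly the `planted_proteins`
  ground-truth set — a disease's curated association row *is* its known
  related-protein list, so injecting noise proteins into the target's
  own row would put items indistinguishable from truth into every
  evaluation. The rank-$r$ disease carries each planted protein with
  probability `overlap_decay`$^r$ (default 0.85, a graded spectrum with
  a few close and many distant diseases) and each background protein at
  rate 0.05, which keeps the table sparse and yields pooled redundancy
  in the 20–60% band of curated tables.
* **GO annotations**: planted proteins draw their 1–3 terms from a
  small deep-term module, background proteins from the whole DAG, so
  annotation-level similarity tracks the designed ladder.
* **Functional network**: strong weights (0.6–0.9) inside the planted
  neighbourhood, weak random ties (0–0.3) elsewhere.
* **Seeds**: 40% of the planted set (a strict subset) is exposed as
  "known", so recovery of the remainder is nontrivial.

Everything is a pure function of `fixture_spec()` and its seed. The
default study conditions — 30 diseases, 300 proteins, 10 planted, seed
42, 400 ensemble rounds, retention threshold 1.5 (the cut between the
designed closeness ladder and the flat tail of the fixture's similarity
distribution), vote threshold 7 — run the full pipeline in seconds and
are the conditions under which the test suite checks planted-protein
recovery. What the fixture does *not* emulate: realistic ontology
topology (real DAGs are bushy, not chains), annotation depth
heterogeneity, curation biases that correlate disease popularity with
protein counts, and protein multi-functionality. Passing tests
demonstrate that the implementation recovers the structure it assumes,
not that the assumptions hold in any particular curated resource.

## Numerical and degenerate-input choices

* MICA ties: lexicographically smallest term id. No common ancestor at
  all: `NA` with IC 0.
* Zero `ic_max` (all terms are roots): Resnik returns 0 rather than
  dividing by zero; Lin guards its denominator the same way.
* Obsolete ontology terms are dropped at parse time and `replaced_by`
  links are not followed; parent links into dropped terms are discarded
  with a warning.
* Cycle detection runs at parse time over `is_a`/`part_of` edges and
  names a cycle member in its error.
* Empty BP term sets score 0 in the PSB surrogate (warning), matching
  the zeros in the published reference table.
* Seed proteins absent from the feature matrix are ignored with a
  warning; a target disease absent from the association table is an
  error.
* An empty retained set after thresholding fails with a stage-named
  error rather than fitting on nothing.

## Limitations

* The PSB and SemFunSim components are surrogates; scores are not
  comparable to the original publications' implementations.
* The headline published result (376 proteins, 308 novel for
  Alzheimer's disease) depended on 2019 releases of the underlying
  databases and is not reproducible from this package alone; the
  package reproduces the method and its printed scalar anchors, not the
  snapshot-dependent protein list.
* With fewer samples than features in every bag, the per-bag
  coefficients are ridge-regularized estimates; their signs and
  magnitudes — and hence the calls — inherit that shrinkage.
* The vote threshold is a resolution parameter, not a significance
  level; no null distribution is attached to call counts.
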