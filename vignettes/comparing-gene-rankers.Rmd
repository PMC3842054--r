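---
title: "Comparing biomarker selection techniques: similarity, stability, and predictive performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing biomarker selection techniques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankstab)
```

## The problem

Biomarker discovery from high-dimensional expression data is routinely cast
as feature selection: given a dataset $D$ with $Z$ samples (tissues,
patients) and $N$ genes, $Z \ll N$, and a binary phenotype, find the genes
most useful for discriminating the two classes. Different selection
techniques applied to the same data generally return *different* gene
signatures, which raises an obvious question: how different, and does it
matter? `rankstab` implements a comparative framework that answers this
along two axes:

1. **Similarity of selected gene sets** — how much do the signatures
   produced by different rankers overlap, both literally (shared genes) and
   functionally (shared Gene Ontology molecular functions)?
2. **Stability and predictive performance** — how robust is each ranker's
   signature to sampling variation, and how well do its signatures classify
   held-out samples?

## Rankers

All eight methods produce a full relevance ordering $L$ of the $N$ genes;
a signature is the top-$t$ cut of that list. Five are univariate (each gene
scored in isolation) and three multivariate:

| name | class | score |
|------|-------|-------|
| `CHI2` | statistic | Pearson $\chi^2$ of the discretized-gene × class table |
| `IG` | entropic | $IG = H(C) - H(C\mid X)$, in bits |
| `SU` | entropic | $2\,IG / (H(C) + H(X))$ |
| `GR` | entropic | $IG / H(X)$ |
| `ONER` | rule-based | training accuracy (%) of a one-gene rule |
| `RELIEFF` | multivariate | nearest-hit/nearest-miss margin weight |
| `SVM_ONE` | multivariate | squared weight $w_g^2$ of one linear-SVM fit |
| `SVM_RFE` | multivariate | reverse order of recursive 10%-per-round elimination |

Conventions that matter and are fixed deliberately:

* **Entropy base 2** throughout, $0 \log 0 = 0$; `GR` is defined as 0 when
  $H(X) = 0$ and `SU` as 0 when $H(C) + H(X) = 0$, so constant genes score
  0 under every criterion rather than producing division errors.
* **Discretization.** The $\chi^2$, entropic, and OneR criteria are defined
  on discrete variables, so each gene is first discretized with supervised
  recursive binary splitting under the minimum-description-length stopping
  rule (Fayyad–Irani): a split at the best information-gain boundary is
  accepted iff its gain exceeds
  $\bigl(\log_2(n-1) + \log_2(3^k-2) - [kH(S) - k_1H(S_1) -
  k_2H(S_2)]\bigr)/n$. Candidate cuts are placed at midpoints between
  *distinct* adjacent values; this is a superset of the class-boundary
  points that can carry the optimum, so the result is identical to the
  boundary-only optimization while remaining robust to tied values.
  Intervals are left-open/right-closed, so a value lying exactly on a cut
  falls in the lower bin. A gene whose best split fails the MDL test
  collapses to a single bin and scores 0 — an aggressive but standard form
  of noise suppression.
* **ReliefF** uses $k = 10$ neighbors (truncated to availability per
  class), all $Z$ instances, Manhattan distance on min–max-scaled values,
  and miss contributions weighted by $P(c)/(1 - P(\mathrm{own}))$.
* **SVM-based rankers** min–max scale genes to $[0,1]$, fit a linear
  soft-margin SVM at $C = 1$, and use $w_g^2$ as importance. `SVM_RFE`
  drops $\lceil 0.10 \cdot \text{survivors} \rceil$ lowest-$w^2$ genes per
  round (at least one, never all), re-fitting in between; the final ranking
  is the reverse elimination order with each dropped batch ordered by
  descending $w^2$. Note this removes 10% *of the survivors* each round —
  a reading of "fraction removed per iteration" that yields many small
  rounds — rather than a constant 10% of the original $N$; the two
  conventions select measurably different signatures on data with many
  near-equivalent markers.
* **OneR** buckets the sorted gene axis with minimum bucket size 6 (the
  classic default), closing a bucket once a class holds a clear majority of
  at least 6 and the next value starts a different class; a deficient tail
  bucket merges backwards. The score is training accuracy of the resulting
  rule. Internal cross-validation variants exist; scoring on the training
  data keeps the criterion deterministic.
* **Ties everywhere** break by ascending original gene index, so every
  ranking is reproducible bit-for-bit.

```{r rank-example}
sim <- generate_dataset(synthetic_spec(n_genes = 200, seed = 1))
rank_features(sim$dataset, "SU")
```

## Similarity of signatures

Two signatures $S_i$, $S_j$ of size $t$ are compared by the overlap index
$|S_i \cap S_j| / |S_i \cup S_j|$ (Jaccard; 0 = disjoint, 1 = identical).
Pairwise comparison of $M$ rankers' signatures gives an $M \times M$
matrix whose off-diagonal mean summarizes the overall agreement. The
chance-corrected Kuncheva index
$(r - t^2/N)/(t - t^2/N)$ is also provided for equal-sized sets; for
signature sizes typical of biomarker panels ($t = 10$ against
$N \geq 2000$) the correction shifts the value by at most $0.005$, which
is why plain overlap is an adequate stability measure in this regime.

Signatures with few or no shared genes can still capture the same biology.
The functional similarity route extracts each signature's molecular-function
GO term set (union over its genes), computes term information content
$IC(u) = -\log_2 p(u)$ with annotation frequencies propagated up the is\_a
graph, scores term pairs by Lin similarity
$2\,IC(\mathrm{MICA})/(IC(u) + IC(v))$, and aggregates with a symmetric
best-match average. Two design choices are deliberate:

* The IC corpus is the supplied annotation map itself — no external
  frequency tables — so results are self-contained and reproducible across
  ontology releases.
* The term-pair measure is pluggable; Lin + best-match-average is a
  transparent, widely used default, but absolute functional-similarity
  values are comparable only within one measure and one annotation corpus,
  and should not be compared against numbers produced by other tools.

An empty term set (a fully unannotated signature) yields a *missing*
similarity, never 0: "no annotation" is absence of evidence, not evidence
of functional dissimilarity.

## The joint stability / performance protocol

From the original dataset, `draw_subsamples()` extracts $P$ reduced
datasets $D_k$ (default $P = 20$), each holding
$\lfloor f \cdot Z \rfloor$ samples (default $f = 0.9$) drawn without
replacement. For each ranker and each threshold $t$:

* **Stability** — rank each $D_k$, cut at $t$, and average the pairwise
  overlap of the $P$ signatures. At $t = N$ stability is exactly 1.
* **Performance** — train a linear SVM ($C = 1$) on $D_k$ restricted to
  the signature and compute the AUC (Mann–Whitney statistic, ties counted
  1/2) of its decision values on the held-out samples $T_k = D \setminus
  D_k$; report mean and SD over $k$.

The ranking on each $D_k$ is computed once and shared by both
evaluations, and the held-out samples never reach the ranker, so the AUC
estimate carries no selection bias — the package's tests verify this
metamorphically by perturbing held-out values and asserting the selected
subsets are unchanged.

Choices the protocol description leaves open, decided here:

* $|D_k| = \lfloor f \cdot Z \rfloor$ — flooring guarantees a non-empty
  test set.
* Draws are **stratified** by class (largest-remainder allocation of the
  per-class quota), so every reduced and held-out set contains both
  classes and every split is trainable; with a 62-sample, 40/22 dataset at
  $f = 0.9$ this gives $|D_k| = 55$, $|T_k| = 7$. Unstratified draws would
  occasionally produce untrainable splits at these sample sizes.
* Splits are independent draws, not cross-validation folds; one master
  seed expands deterministically into per-split seeds, so any split can be
  reproduced in isolation.

```{r protocol-example}
scheme <- draw_subsamples(sim$dataset, p_count = 5, seed = 42)
je <- joint_evaluation(sim$dataset, c("SU", "RELIEFF", "SVM_RFE"), scheme,
  thresholds = c(5, 10)
)
tidy(je)
```

## What the synthetic generator emulates — and what it does not

`generate_dataset()` mirrors the statistical silhouette of classic
two-class microarray benchmarks: tens of samples, hundreds to thousands of
genes, a handful of truly informative genes, and blocks of redundant
correlated markers. Background genes are i.i.d. Gaussian; informative genes
get a mean shift of `effect_size` SD units in the positive class; each
redundant block shares a latent informative signal
($g = \sqrt{\rho}\,L + \sqrt{1-\rho}\,\varepsilon$), giving within-class
pairwise correlation $\rho$ and unit marginal variance. Labels are assigned
deterministically (exact class proportions) and rows shuffled under the
seed.

Defaults — 60 samples, 1000 genes, 10 informative genes at effect size 2
SD, balanced classes — were chosen once as a realistic small-benchmark
regime: effect size 2 at $n \approx 30$ per class corresponds to per-gene
two-sample $t$-statistics around 7–8, i.e. markers that are individually
strong but not trivially dominant against 990 background genes.
`redundant_spec()` fixes the redundancy scenario: 300 genes, 4 independent
markers plus two blocks of 5 markers at $\rho = 0.9$, so a size-10
signature must choose among 14 near-interchangeable ground-truth genes.
This reproduces the characteristic dissociation — recursive elimination
keeps sparse block representatives that differ from subsample to
subsample (low stability, intact AUC), while margin-based ReliefF scores
all block members highly and selects them consistently.

The generator deliberately does **not** model probe-level artifacts, batch
effects, heavy-tailed intensity distributions, or nonlinear class
structure. Passing the simulation-based tests therefore demonstrates that
the machinery is correct and that the redundancy mechanism behaves as
described, not that any particular ranker will be stable on real
microarray data.

## Numerical choices and degenerate inputs

* Expression files with missing values are rejected, never imputed —
  silent imputation would change rankings in ways invisible to the user.
* The lexicographically smaller class symbol is the negative class unless
  overridden; AUC orientation depends on it, so it must be deterministic.
* Loaders apply no preprocessing (no log-transform, no thresholding);
  what is in the file is what is ranked.
* Constant genes: discretize to one bin, score 0 under all univariate
  criteria, min–max scale to 0 for the distance/SVM-based methods.
* Empty gene sets are rejected by the overlap index; Kuncheva requires
  equal sizes and $t < N$ (at $t = N$ the index is undefined).
* Simulation sizes in the test suite are scaled to the smallest problems
  that exercise each property (e.g. recovery studies over 20 generator
  seeds at $60 \times 1000$ with $P = 2$ subsamples; the redundancy
  contrast at $60 \times 300$ with $P = 10$).

## Known limitations

* The univariate scorers depend on the discretization; a different
  discretizer (or none, as in implementations that bin internally with
  other defaults) will change absolute scores and can perturb rank order
  near the cutoff, so cross-tool comparisons should compare *protocols*,
  not raw numbers.
* `SVM_RFE`'s proportional elimination performs many refits; on data with
  many near-equivalent markers each refit redistributes weight among them,
  which makes the tail of the top-$t$ boundary genuinely unstable — the
  phenomenon the framework is designed to expose, but also a property of
  the algorithm itself, not noise to be averaged away.
* Functional similarity values are only comparable within one ontology
  file, one annotation corpus, and one term-pair measure.
* The protocol is binary-class only; multiclass AUC and k-fold
  cross-validation variants are out of scope.
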