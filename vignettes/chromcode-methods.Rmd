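---
title: "chromcode: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromcode: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcode)
```

# The model

chromcode represents the chromatin signature of each genomic locus as a
non-negative superposition of a small number of basis patterns ("codes").
Given a non-negative signal matrix $V$ (loci $\times$ marks), it solves

$$\min_{W, H \ge 0} \;\; \lVert V - WH \rVert_F^2 \;+\; \lambda \sum_{kj} H_{kj}$$

where $H$ ($c \times m$) holds the codes and $W$ ($n \times c$) the
per-locus weights. Non-negativity is what makes the decomposition
interpretable: a code is a set of marks that rise together, and a locus is
a weighted sum of codes, with no cancellation between positive and negative
parts as in PCA. The L1 penalty acts on $H$ only, so sparsity is pushed
into the code definitions (few marks per code) rather than into the locus
weights, where superposition of several codes per locus is expected and
desirable.

## Assumptions

* Signals are quantified as read counts over user-defined loci; the method
  assumes the loci are meaningful units (promoter windows, peak regions)
  and does not segment the genome itself.
* Within the absolute and discriminatory modes, the enrichment of a mark
  within a locus is summarized by a single number; spatial profile shape
  inside the locus is deliberately ignored.
* Differential mode assumes exactly two conditions with the same marks and
  that library-size differences are well captured by median-of-ratios size
  factors computed on the window grid.

# Quantification and normalization

**Read counting.** A read contributes to a locus if its aligned reference
span (start to end, including deletions and splice gaps) overlaps at least
one base. Unmapped, secondary, supplementary and QC-fail records are
excluded; duplicates are kept by default (`filter_dup = TRUE` removes
them, `min_mapq` adds a mapping-quality floor). Strand is ignored, and a
read overlapping $k$ loci counts towards all $k$ — per-locus counts are
independent sums. There is no fragment-size extension or paired-end
reconstruction: each mapped record counts once.

**Sigmoid scaling.** Every column $x$ of the count matrix is mapped to
$[0, 1)$ by

$$\hat x = \frac{2}{1 + e^{-2x/u}} - 1,$$

with $u$ the 95th percentile of $x$ (linear-interpolation percentile; the
estimator had to be fixed because percentile conventions differ). The map
is approximately linear up to $u$ and saturates above it, so the top 5% of
loci cannot dominate the factorization; it is exactly invariant to
rescaling $x$ by any positive constant. Degenerate columns are handled
explicitly: an all-zero column is returned unchanged with a warning, and a
column that is zero at the 95th percentile but not everywhere falls back
to the smallest positive value as $u$.

**Size factors and gain/loss integration (differential mode).** For each
mark, both conditions are counted on the same non-overlapping window grid
inside each locus (`window` parameter, default 100 bp — a single width
parameter; windows never overlap). Size factors come from the DESeq
median-of-ratios estimator on the pooled two-column window-count matrix,
computed per mark because ChIP libraries differ per antibody. The
depth-corrected per-window difference $d_w = B_w/s_B - A_w/s_A$ is then
integrated into $\text{gain} = \sum_w \max(d_w, 0)$ and
$\text{loss} = \sum_w \max(-d_w, 0)$. Both are stored as non-negative
magnitudes so the NMF non-negativity constraint applies directly, and
gain $-$ loss always equals the net depth-corrected change. The windowed
formulation matters because differential signal is not strongly
auto-correlated: a peak that merely broadens loses coverage at its summit
while gaining at its slopes, and integrating signed window differences
separates that case (gain > 0 *and* loss > 0) from a uniform gain or loss.
Differences below $10^{-8}$ of the corrected count scale are snapped to
zero: this is float rounding, and the later column scaling would otherwise
amplify pure rounding residue of identical libraries to full scale.

# Optimization and initialization

The objective is minimized by HALS-style block coordinate descent: each
column of $W$ and each row of $H$ is minimized exactly in closed form in
turn. Exact per-block minimization makes the penalized objective
non-increasing at every sweep (asserted in the tests) and, unlike
multiplicative updates, cannot lock entries at zero — which matters
because the default initialization contains exact zeros.

Defaults, all overridable:

| parameter  | default | meaning |
|------------|---------|---------|
| `l1_H`     | 0.1     | L1 weight on H, tuned for data scaled to [0, 1) |
| `max_iter` | 500     | outer sweep limit |
| `tol`      | 1e-4    | relative change of the penalized objective that stops iteration |
| `init`     | nndsvd  | deterministic initialization |

The reported `reconstruction_error` is the *unpenalized* Frobenius norm
$\lVert V - WH\rVert_F$, so runs with different penalties are comparable.

**NNDSVD.** The initialization takes the truncated SVD of $V$, uses the
absolute values of the leading singular pair, and splits every further
singular-vector pair into positive and negative parts, keeping the pair
with the larger product of norms rescaled by the singular value. Ties
between the positive and negative parts resolve to the positive part, so
the construction is fully deterministic: two runs on the same matrix are
bitwise identical. The `nndsvdar` variant replaces the exact zeros of this
construction with small uniform values in $(0, \text{mean}(V)/100]$ under
a seed. All-zero rows of $V$ are retained (their $W$ rows converge to
zero) so that row indexing always matches the input region set.

**Initialization comparison.** On the package's planted benchmark
(below), NNDSVD gives a solution whose error is no worse than the median
of 100 random initializations. At this benchmark size every
initialization converges to the same optimum, so observed error
differences sit at the level of float noise far below the convergence
tolerance; the comparison is therefore made at the optimizer's resolution
(relative slack equal to `tol`), since solutions closer than the stopping
tolerance are indistinguishable by construction.

**Rank choice.** `rank_scan()` reruns the factorization across a range of
$c$ with identical settings and reports the mean Hoyer sparsity of the
rows of $H$ and of $W$ plus the reconstruction error. Hoyer sparsity,
$(\sqrt n - \lVert v\rVert_1 / \lVert v\rVert_2)/(\sqrt n - 1)$, is 0 for
a constant vector and 1 for a one-hot vector. No automatic selection is
attempted: the intended use is to locate the knee where additional codes
begin to degenerate into single-mark rows. At $c = 1$ the rows of $W$
have length one, where the measure is undefined, and `NA` is reported.

# The three modes

**Absolute** is the composition count $\to$ scale $\to$ factorize.

**Discriminatory** factorizes each class of loci separately (class-specific
sigmoid scaling, since each class is its own data set), concatenates the
per-class bases into one $H$ with provenance-carrying labels
(`<class>:code_<j>`), and re-derives a single $W$ over all loci by row-wise
non-negative least squares against the combined $H$. Each class's own
scaled submatrix enters the joint NNLS — the scaling that produced a
class's codes is the scaling under which those codes are meaningful. If
the classes share their latent structure the class-specific codes are
interchangeable (cross-class NNLS residuals comparable to within-class
ones, and hard-assignment class purity near chance); if not, codes are
discriminatory and loci load on their own class's codes. With a single
class the mode reduces exactly to the absolute algorithm, up to the NNLS
re-derivation of $W$ (equal within the optimizer's resolution). The rank
is the same for every class by default and overridable per class.

**Differential** composes windowed counting, size-factor correction and
gain/loss integration per mark, column-scales the $n \times 2m$ gain/loss
matrix (`<mark>.gain`, `<mark>.loss` interleaved) and factorizes it. Codes
are then patterns of *coordinated change* — a gain of one mark can load
together with a loss of another. If the two conditions are identical the
matrix is exactly zero and the factorization refuses to run; the error is
deliberate, as there is nothing to decompose.

# Post-processing

* **Hard assignment**: each locus gets the code with its maximal weight;
  ties break to the lowest code index; an all-zero row is reported
  unassigned. The margin to the runner-up is reported so soft cases are
  visible.
* **Code matching**: codes from two factorizations are paired by
  minimum-total-cost assignment (Hungarian algorithm) on the Euclidean
  distance between basis rows; plain distances by default, since matched
  factorizations normally share a scale. A unit-L2 option exists for
  cross-data-set comparisons; with unequal ranks, a rectangular assignment
  is solved on the smaller side and leftover codes are reported as
  singletons. For small ranks the result is verified in the tests against
  the exhaustive permutation minimum.
* **Multicollinearity report**: pairwise Spearman correlations of mark
  columns or of code weight columns; pairs with $|\rho| > 0.8$ are
  flagged as unsuitable to enter one regression together. Constant
  columns yield a correlation of 0 and are listed separately rather than
  propagating `NA`.

# Gene-set enrichment

Each code's $W$ column scores the loci; loci are mapped to genes through
the BED name field (or an explicit map), with multiple loci per gene
averaged. For a set with $m$ scored members out of $N$ genes, the mean
set score $\bar X$ is compared with its exact moments under sampling
without replacement:

$$E[\bar X] = \mu, \qquad
  \mathrm{Var}[\bar X] = \frac{\sigma^2}{m}\,\frac{N - m}{N - 1},$$

with $\mu, \sigma^2$ the population mean and variance of all scores, and
$z = (\bar X - \mu)/\mathrm{sd}$ referred to the standard normal,
upper-tailed by default since positive association is the question being
asked (a two-sided option exists). The finite-population variance was
chosen over the infinite-population form and is validated against a
permutation oracle in the tests rather than against a formula reference.
Degenerate inputs follow a "no evidence" convention: a zero-variance score
vector yields $z$ undefined and $p = 1$, and sets with no scored member
are skipped with a note. Raw weights are used without rank transformation.
All (code, set) p-values are corrected jointly by Benjamini–Hochberg — the
stricter family — with per-collection reporting left to filtering.

The normal approximation is a large-$m$ device: for very small sets
(roughly $m < 10$) or extremely skewed score vectors its tail accuracy
degrades, which is why the test suite validates it on a symmetric score
population where the approximation error is provably below Monte-Carlo
resolution, and why empirical calibration on shuffled scores is asserted
separately.

# The synthetic benchmark

`make_planted_matrix()` draws $V = W^* H^* + \varepsilon$, clipped at zero
and sigmoid-scaled, with known factors. Its defaults define the study
conditions used throughout the tests: $n = 200$ loci, $m = 8$ marks,
$c = 3$ codes, noise $\sigma = 0.05$ (and $\sigma = 0$ for exact-recovery
checks). Design features, chosen to emulate the structure the method
targets:

* each code has exactly 3 dominant marks (uniform in [0.6, 1]) on rotated
  supports, plus moderate background loadings (uniform in [0.05, 0.3])
  with probability `1 - sparsity` (default `sparsity = 0.65`) — marks
  participate in several codes, as real marks do, which is what makes raw
  mark columns *more* correlated than code weight columns;
* codes activate independently across loci: one primary code per locus
  with an occasional secondary (probability 0.3), weights heavy-tailed
  (shifted exponential) so most scaled entries stay in the near-linear
  range of the sigmoid. Independent activation matters: mutually
  exclusive activation would itself induce strong negative correlations
  among $W$ columns and destroy the de-correlation property the benchmark
  is meant to exhibit.

Because the factorization operates on the *scaled* matrix, the truth
record carries `H_scaled` — the planted basis with each column divided by
that column's sigmoid scale $u$ — and recovered codes are compared against
that representation; comparing against the raw $H^*$ would conflate
recovery error with the (known, deliberate) column scaling.

`make_two_class_fixture()` plants disjoint *dominant* supports for the two
classes (first vs second half of the marks) with small background loadings
on the other half. The background is essential, not cosmetic: per-class
sigmoid scaling normalizes every column to its own dynamic range, so a
mark with no structured signal in a class would be amplified pure noise,
which the other class's codes would then absorb in the joint NNLS. With
`shared = TRUE` both classes use one basis, a control under which class
purity collapses to chance.

`make_toy_alignments()` writes deterministic miniature data sets — 36 bp
single-end perfect alignments on a synthetic 100 kb contig named `chrS`
(avoiding collision with real genome names), sorted and indexed, with a
matching BED and a machine-readable truth table — for three scenarios:
planted mark co-occurrence (absolute), a duplicated library (size-factor
ratio exactly 2, all gains and losses zero), and a broadened peak (losses
at the summit, gains at the slopes of the focal locus).

**What passing these benchmarks does and does not show.** The generators
emulate sparse non-negative structure, library-depth asymmetry, window
integration and overlap counting. They do not model ChIP fragment-length
effects, GC or mappability bias, replicate variance, spatial
auto-correlation of signal, or antibody efficiency differences. Passing
the recovery and calibration tests therefore demonstrates correctness of
the algorithms under their own assumptions, not performance on any
particular real data set.

# Problem sizes used by the test suite

The suite runs at desk scale: recovery over 10 generator seeds of the
200 x 8 benchmark, 100 random initializations for the initialization
comparison, exhaustive permutation matching up to rank 6, a $2 \times
10^5$-draw permutation oracle for one enrichment case, and 1000 random
sets for null calibration. Everything completes in well under a minute
per file on one core.

# Known limitations

* At most two conditions in differential mode; no time courses.
* No automatic rank selection, consensus NMF, or model-based uncertainty
  on $H$ and $W$.
* No peak calling, input-control subtraction, quantile normalization or
  GC correction; inputs are taken as given.
* Locus-to-gene mapping for enrichment is by identifier matching only; no
  identifier-translation service is included.
* The random-set z-test relies on a normal approximation; for very small
  sets a permutation p-value is the safer choice.
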