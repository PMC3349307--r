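---
title: "Gapped dinucleotide profiles: the method behind dinuprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapped dinucleotide profiles: the method behind dinuprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinuprof)
```

## The descriptor

`dinuprof` compares DNA sequences without alignment, through a composition
descriptor that keeps some of the positional information ordinary k-mer
counts discard.  For a sequence $s$ of length $n$ over $\{A,C,G,T\}$ and a
separation distance $d \ge 1$, count every ordered pair $XY$ with $X$ at
position $i$ and $Y$ at position $i+d$ ($d = 1$ means adjacent; a position
may serve as $X$ for one pair and $Y$ for another).  There are $n - d$ such
pairs, so the counts $XY^{(d)}$ normalize to frequencies

$$ f_{XY}^{(d)} = \frac{XY^{(d)}}{n - d}, $$

a point on the 16-simplex for each $d$.  The 16 ordered pairs are kept in
one frozen order (`dinucleotides()`), starting `AT, AA, AC, AG, ...` and
ending `CC, CG`; the order is arbitrary for any distance computation but
fixing it makes every serialized profile reproducible byte for byte.
Pairs are *ordered* — `AT` and `TA` are distinct — so the descriptor is
strand-specific, and deliberately so: no reverse-complement
canonicalization is applied anywhere.

Stacking the frequency rows for $d = 1, \dots, d_0$ gives the $d_0 \times
16$ **frequency matrix** $F(s)$; unrolling it row-major (smallest $d$
first) gives the $16\,d_0$-dimensional **profile vector** $\hat F(s)$.

## Why $d_0 \le \lfloor n/4 \rfloor$

At separation $d$ the $X$ window is $[1, n-d]$ and the $Y$ window is
$[d+1, n]$.  Requiring that at least half of all positions lie in both
windows, $(n - 2d)/n \ge 50\%$, bounds the separation by $\lfloor n/4
\rfloor$ (`max_valid_distance()`).  For a set of sequences the shared
depth is the minimum of this bound over the set (`common_depth()`), so all
matrices have one shape and can be compared cell by cell.  Longer
sequences are never truncated: all of their residues contribute pairs to
every layer $d \le d_0$.  A larger depth (up to $n-1$) can be forced with
`enforce_bound = FALSE`, which warns that the overlap guarantee is lost.

## Distances

Two dissimilarity measures are defined on the descriptors:

* **city-block** $d_1(s,h) = \sum_{i,j} |F_{ij}(s) - F_{ij}(h)|$ — a true
  metric (the triangle inequality is property-tested);
* **cosine** $d_2(s,h) = 1 - \cos(\hat F(s), \hat F(h))$ — in $[0,1]$ on
  non-negative vectors, zero for parallel vectors, scale-invariant, and
  *not* a metric (no triangle inequality is asserted).

Accumulation order is fixed row-major (separation, then pair), so repeated
runs are bit-identical.  `pairwise_distances()` assembles the full
symmetric matrix in input order; output order is never alphabetized, so
rows align with the customary presentation of the benchmark below.

## The beta-globin benchmark

`beta_globin()` bundles the first coding exon of the hemoglobin beta gene
for 11 species (Human, Chimpanzee, Gorilla, Lemur, Rat, Mouse, Rabbit,
Goat, Bovine, Opossum, Gallus; lengths 86–105 nt), a classic test set for
alignment-free descriptors.  The shortest member (86 nt) fixes the shared
depth at $d_0 = 21$, so each sequence is a $21 \times 16$ matrix or a
336-dimensional vector.

```{r benchmark}
bg <- beta_globin()
common_depth(bg)
D1 <- pairwise_distances(bg, "d1")
round(D1[1:4, 1:4], 4)
```

The biologically expected structure emerges on both metrics: the smallest
distances are within the great-ape trio (Human, Chimpanzee, Gorilla) and
the Goat–Bovine pair (both Bovidae); the largest separate Gallus — the
only non-mammal — and Opossum — the only marsupial — from the rest, with
the single largest entry at Lemur–Gallus.  The two metrics agree in rank
(Spearman correlation above 0.98 on the 55 pairs).

Two data caveats, for users who compare against printed tabulations of
this benchmark:

* The Mouse record circulates in some printed copies with a
  typographically duplicated `T` near the 5' end (94 nt); the bundled copy
  is the 93-nt version consistent with the accession's reported length,
  and it — not the 94-nt variant — reproduces the classic distance values
  involving Mouse.
* The Gorilla record as circulated is byte-for-byte the Human sequence
  plus one trailing `G`.  Under any composition descriptor the two are
  then nearly indistinguishable ($d_1 \approx 0.46$, $d_2 \approx 0.0008$
  here), whereas classic tabulations of this benchmark print Human–Gorilla
  values of the same order as Human–Chimpanzee ($d_1 = 2.4026$,
  $d_2 = 0.0074$).  Those printed values cannot be produced from the
  circulated Gorilla string: every non-Gorilla entry of the classic tables
  reproduces here to the printed four decimals, while no plausible variant
  of the Gorilla string (case, orientation, frame shifts, nor a direct
  search over nearby sequences) yields the printed Gorilla column.  The
  package keeps the circulated sequence and reports what it actually
  computes rather than patching the fixture toward the printed numbers.

## Relative similarity and PCA

`relative_similarity()` rescales one row of a distance matrix by a chosen
reference pair (customarily Human–Gorilla, which then maps to exactly 1),
a convenient way to compare the two metrics' rankings on one axis.

`pca_project()` examines how much of the profile-vector variation is
low-dimensional.  Design choices, since several conventions exist:

* **Covariance PCA, not correlation.**  All $16 d_0$ features are
  frequencies on one scale, so columns are mean-centered but not rescaled.
  On the benchmark the top two components carry 48% of the total variance
  (the check of this convention); the correlation variant would give a
  materially lower figure and is not used.
* **SVD of the centered matrix**, numerically preferable to forming the
  covariance matrix; explained fractions are $\sigma_i^2 / \sum_k
  \sigma_k^2$ with the null direction forced by centering dropped.
* **Sign convention:** each loading vector is flipped so its
  largest-magnitude entry is positive, making plots reproducible (PCA
  axes are otherwise defined only up to sign).

```{r pca}
p <- pca_project(bg, k = 2)
round(100 * p$explained[1:3], 1)
```

In the 2D projection Gallus and Opossum are the two points furthest from
the centroid and the great-ape trio sits tightly together — the same
structure the distance matrices show.  The projection is a lossy summary:
with only 48% of the variance in two components, 2D proximities can
disagree with full-dimensional distances for mid-range pairs, and tests
assert only the rank properties above, never coordinates.

## Degenerate inputs and numerical notes

* Sequences shorter than 4 nt admit no valid separation and are rejected
  at construction.
* Uppercasing is the only silent normalization.  Any character outside
  A/C/G/T is a hard error by default, naming the record, character and
  position.  The opt-in `skip` policy (CLI `--ambiguous skip`) instead
  drops every pair touching a non-ACGT position from both the numerator
  and the denominator, so frequencies still sum to 1 over retained pairs.
* `cosine_distance()` refuses zero vectors (unreachable from valid
  profiles, whose entries sum to $d_0 \ge 1$).
* PCA refuses sets with zero total variance (all vectors identical).
* Printed precision (`--precision`, default 4) affects output formatting
  only, never internal arithmetic.

## What the tests do and do not show

The test suite checks the counting core against naive position-by-position
oracles on hundreds of random uniform-composition sequences (fixed seeds),
the metric axioms on random simplex profiles, and the benchmark numbers
above.  Random uniform DNA is a deliberately featureless null — it has no
codon structure, repeats or compositional skew — so these tests establish
algorithmic correctness, not biological performance; the benchmark
provides the latter only for one short, well-studied locus.  Problem sizes
(11 sequences of ~100 nt, 336 features) make every computation here
essentially instantaneous; the package is equally applicable to much
longer sequences since counting is linear in $n$ per layer.

## Limitations

* The descriptor is strand-specific and position-free beyond the pair
  separation; it will not distinguish sequences with identical gapped
  pair statistics.
* No $k > 2$ generalization, no additional metrics, and no tree inference
  are provided; the PHYLIP writer exists solely so downstream tools can
  consume the distance matrices.
* Accession numbers in the bundled benchmark are metadata only; nothing
  is fetched from NCBI.
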