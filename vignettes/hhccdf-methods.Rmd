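---
title: "Counting ranks instead of differencing means: the HH-CCDF association scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting ranks instead of differencing means: the HH-CCDF association scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhccdf)
```

## The problem

A genome scan asks, marker by marker, how strongly a categorical genotype
score (e.g. `0/1/2` dosages, `-1/0/1` bin scores) is associated with a
quantitative trait. The quantity of real interest is the *gene signal* — the
genetic contribution to the phenotype — but only the phenotype is observed,
and it is at best an imperfect, often nonlinear readout of that signal. Any
statistic built on class means (the one-way F test, sum-based coefficients)
inherits this distortion: a few extreme phenotypes move a class mean a lot,
so apparent effect sizes stop tracking signal magnitudes.

The HH-CCDF sidesteps the mean. It asks a counting question: *of the
top-ranked trait values, how many sit in the genotype classes with higher
averages?* Each observation then contributes exactly one count, whether it is
extreme or barely above the cut, and the resulting class distance is robust
to monotone distortion of the phenotype scale.

## The statistic

For one marker on `N` individuals with `n` observed genotype classes:

1. **Hierarchical stratification.** Order the classes by ascending class
   phenotype mean. Mean ties are broken by ascending lexicographic sort of
   the class label text — the data give no preference, and a total order is
   required for reproducibility.
2. **Hierarchical binary categorization.** Each of the `n − 1` ordered class
   boundaries collapses the marker into a binary split; the right
   (higher-mean) side is the subset `s1`, of size `d_x`.
3. **Boundary count.** `k_x` is the size of the *multiset* intersection
   between the `d_x` largest trait values in the whole population and the
   trait values of the individuals in `s1`. Tied values are matched up to
   their minimum multiplicity on the two sides, which is equivalent to
   choosing, among all rank orderings consistent with the ties, the one that
   maximizes the intersection. `boundary_counts()` exposes the
   `(N, d, K, k)` quadruple per boundary.
4. **Boundary tail.** With `K_x = d_x`, the boundary's P value is the
   hypergeometric complementary cumulative tail
   `P(X > k_x)` for `X ~ Hypergeometric(N, K_x, d_x)` (`hccdf_tail()`): the
   probability that a random `d_x`-subset would capture more of the top
   values than the observed classes did.
5. **Combination.** The marker's P value (`hh_ccdf()`) is the geometric mean
   of the `n − 1` boundary tails, computed in log space. If any boundary
   achieves a perfect split (`k = d`, tail exactly 0) the combined value is
   exactly 0 — no smoothing is applied, preserving the
   "perfect association → P = 0" limit; the display layer floors the
   `-log10` transform instead (default floor `1e-300`, so an exact zero
   plots as 300).

The summation bound in the tail deserves a note: written as a complementary
CDF the sum must stop at the *observed* count `k`; summing the full support
would make every tail identically zero. `hccdf_tail()` treats out-of-support
terms as zero, so `k ≥ min(K, d)` returns 0 and `k` below the support minimum
`max(0, K + d − N)` returns 1. Terms accumulate as exponentials of
log-gamma binomial coefficients, summed over the upper tail directly (not as
one minus the lower sum), which keeps small tails at full relative precision
and avoids overflow for populations in the thousands.

## Companion methods

Two comparators run on the same stratification:

* **One-way F test** (`f_test()`): the fixed-effects decomposition
  `y_ij = μ + α_i + ε_ij`, fitted via `lm()`/`anova()`, with the exact
  F-distribution upper tail as the P value.
* **HA coefficient** (`ha_coefficient()`): with `y` the total trait sum and
  `f(t) = y·ln(t) − t`, each boundary contributes
  `(f(obs) − f(btm)) / (f(top) − f(btm))`, where `obs`, `top` and `btm` are
  the `s1` sums under the observed, top (ascending within and across
  classes) and bottom (descending) categorizations; the coefficient is the
  geometric mean of the ratios. It is 1 when the observed arrangement *is*
  the top categorization and 0 at the bottom categorization. Because
  `f` requires strictly positive arguments, the operation refuses
  non-positive trait values rather than silently rescaling; the scan layer
  applies min–max normalization (`normalize_minmax()`, mapping onto
  `[0, 1]`) automatically only when non-positive values are detected, with a
  warning, and explicit flags override. One subtlety follows from the
  definitions: since stratification orders classes by their *observed*
  means, the observed arrangement can never literally be the bottom
  categorization, so the 0 endpoint is a property of the formula, exposed
  for verification through `ha_from_sums()` on synthetic sum tables.

## The scan layer

`scan_markers()` applies any subset of the three methods column by column
and returns one row per marker in input order, with `-log10` P columns for
the two tests. Markers left with fewer than 2 classes after missing-data
removal are reported with `status = "degenerate"` and `NA` statistics — "no
test performed" is deliberately distinct from "no evidence" (P = 1).
`normalize_scores()` min–max rescales any score column for cross-method
overlays. Results serialize to TSV with `#`-prefixed metadata lines
(`write_scan_tsv()`); a thin command-line wrapper with `scan`, `simulate`
and `demo` subcommands ships in `inst/cli/hhccdf.R`, logging to stderr and
writing results only to the output stream.

## The simulator and what it emulates

`triangle_sim_config()` describes the benchmark design: a
`n_individuals × n_markers` table (defaults 500 × 450) of i.i.d. uniform
`{0,1,2}` noise, with three 150-marker blocks each carrying a pair of
vertically symmetric triangles — 0s filling the top rows, 2s the bottom rows,
with linearly tapering depth `round(h·(1 − |j − c|/75))` away from the
block's tip column `c` and heights 20, 30, 40 left to right. The phenotype
rises 1, 2, …, 40, plateaus at 40, then rises 41, …, 80 over the last 40
individuals. The triangle rows tie genotype to the phenotype extremes, so
triangle height is a visual, controllable gene-signal magnitude, while the
plateau emulates the saturated mid-range where phenotype stops responding to
signal. With even block width the tip sits one column right of the block
centre (a single tip column, matching the design's dashed-line convention);
alternative symmetric-tip conventions would shift peaks by at most one
column and are not configurable.

`run_simulation()` repeats generate–scan `n_reps` times and averages
per-marker *scores* — `-log10` P for the two tests, the raw coefficient for
HA — rather than raw P values, since profile plots live on the score scale.
A master seed spawns per-replicate child seeds deterministically, so any
replicate can be regenerated in isolation.

What passing simulation tests do **not** show about real data: the generator
has no linkage structure, no polygenic background, no phenotype noise beyond
the plateau construction, and a heavily tied, rank-valued phenotype. It is a
controlled magnitude-recovery benchmark, not a realism model.

### A known limitation at the tallest signal

The tie rule interacts sharply with the plateau. At the right block's tip
column the bottom triangle (height 40) covers exactly the 40 individuals of
the rising phenotype tail, and every remaining member of the top-`d` multiset
is a plateau tie; the maximal tie-consistent intersection then reaches
`k = d` at *both* boundaries, the tails are exactly 0, and the marker's
`-log10` score sits at the floor (300) in every replicate. Mean peak heights
under the default design are therefore approximately 99, 118, 300 (25
replicates) instead of increasing at nearly regular intervals: the middle
increment (~18) and the right increment (~182) differ far more than 30%.
The package's acceptance suite asserts the regular-increment property and
this test fails by design of record: the tie rule is pinned by the worked
example (it is required to reproduce the boundary count `k = 5` and the
final P value 0.059), and we chose fidelity to the defined statistic over
tuning any component to make the profile regular. A tie resolution that
assigns tied individuals in storage order would avoid the saturation but
contradicts both the defined maximal-intersection count and the worked
example. Users comparing peak magnitudes on heavily tied phenotypes should
treat floored scores as censored values.

## Numerical and design choices

* **Worked-example ordering.** Classes are ordered by class mean throughout.
  On the bundled 20-individual example this yields boundary counts
  `(d, k) = (14, 10)` and `(8, 5)` and the P value 0.059; an ordering by
  raw label would give `(6, 2)` at the upper boundary and is not
  implemented, as it contradicts the mean-ordering definition.
* **Exactness.** `hccdf_tail()` agrees with exact integer enumeration to
  `< 1e-10` over the entire `N ≤ 25` grid (the test suite checks all ~65 000
  cases, plus `phyper()` as an independent cross-check) and is strictly
  decreasing in `k` with the `(K, d)` symmetry of the hypergeometric law.
* **Degenerate inputs.** Single-class markers, empty id joins, constant
  phenotypes, non-positive HA inputs and invalid count quadruples each raise
  a distinct classed condition (`hh_error_*`), so callers and the CLI can
  branch on cause.
* **Problem sizes.** The test suite exercises the simulator at full design
  size (500 × 450) with 10 and 25 replicates for the profile properties and
  scaled-down designs elsewhere; a single full scan of 450 markers with all
  three methods takes about two seconds, and the 278 × 1617 bin-score data
  shape is covered by a synthetic format-level fixture generated at test
  time.

## Limitations

No covariate adjustment, kinship/structure correction, multiple-testing
adjustment, or genomic coordinates: markers are unordered columns, and the
statistic is a per-marker measure. Tied phenotypes are handled by the
maximal tie-consistent intersection; a minimum-consistent alternative would
give systematically larger P values on tied data and is not offered.
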