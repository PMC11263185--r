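---
title: "M-polynomial operator calculus, polysaccharide families, and QSPR models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{M-polynomial operator calculus, polysaccharide families, and QSPR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpolyindex)
```

## The model

A hydrogen-suppressed molecular graph $\Gamma$ reduces a molecule to its
heavy-atom skeleton; the degree $d_v$ of a vertex counts heavy-atom
neighbours.  Every *degree-based topological index* in this package depends
on $\Gamma$ only through its **degree-pair edge partition**: the map
$(s,t) \mapsto m_{st}$, $s \le t$, counting the edges whose endpoint degrees
are $\{s,t\}$.  The **M-polynomial**

$$ M(\Gamma; x, y) = \sum_{s \le t} m_{st}\, x^s y^t $$

encodes the partition as a generating polynomial, and each index is obtained
by applying a short chain of operators to it and evaluating at $x = y = 1$:

| Index | Edge-sum kernel | Operator chain |
|---|---|---|
| $M_1$ | $s+t$ | $(D_x + D_y)$ |
| $M_2$ | $st$ | $D_x D_y$ |
| $^mM_2$ | $1/(st)$ | $S_x S_y$ |
| $R_\alpha$ | $(st)^\alpha$ | $D_x^\alpha D_y^\alpha$ |
| $RR_\alpha$ | $(st)^{-\alpha}$ | $S_x^\alpha S_y^\alpha$ |
| $SDD$ | $s/t + t/s$ | $D_x S_y + S_x D_y$ |
| $H$ | $2/(s+t)$ | $2\, S_x J$ |
| $I$ | $st/(s+t)$ | $S_x J D_x D_y$ |
| $AZI$ | $\big(st/(s+t-2)\big)^3$ | $S_x^3 Q_{-2} J D_x^3 D_y^3$ |

with $D_x = x\,\partial/\partial x$, $S_x f = \int_0^x f(t,y)/t \, dt$,
$J$ the diagonal substitution $g(x,y) \mapsto g(x,x)$, and $Q_\alpha$ the
exponent shift $g \mapsto x^\alpha g$.  Chains are applied right to left.
The package implements both routes — `direct_index()` (edge sums) and
`index_from_operators()` (operator calculus on a sparse `bipoly`) — and the
test suite holds them equal on hundreds of random chemical graphs; the dual
route is the package's main correctness argument.

Two conventions deserve a note:

* **$R_\alpha$ sign.**  The literature writes the general Randić index both
  as $\sum (d_u d_v)^\alpha$ and as $\sum (1/(d_u d_v))^\alpha$.  This
  package fixes $R_\alpha = \sum (st)^\alpha$ and
  $RR_\alpha = \sum (st)^{-\alpha}$, the convention realised by the operator
  table ($D_x^\alpha D_y^\alpha$) and by the closed-form results it
  reproduces; $R_{-1/2}$ is then the classic Randić index and
  $^mM_2 = R_{-1}$.
* **Operator vs. index $I$.**  The diagonal-substitution operator is called
  $J$ here, so that $I$ unambiguously names the inverse-sum-indeg index.

## Numerical design

Coefficients and exponents of `bipoly` terms are exact rationals (a small
numerator/denominator layer, reduced by gcd at every step); conversion to
floating point happens only at final evaluation.  All nine named indices use
integer-power operators, so their values — and the recomputed carbohydrate
index table — are exact before presentation rounding.  Fractional $\alpha$
in $R_\alpha$/$RR_\alpha$ produces irrational per-term factors; those are
carried as plain doubles from that point on, and the two routes then agree
to floating-point accuracy rather than exactly.

Presentation rounding is half-up to 4 decimals (`round_half_up()`), matching
how tabulated index values are conventionally printed; base R's
round-half-even would differ on ties.  Rounding never feeds back into
computation or comparisons.

The AZI kernel divides by $(s+t-2)^3$, which vanishes for an edge joining
two degree-1 vertices.  Both routes surface this identically: the edge sum
refuses the partition, and in the operator chain the $(1,1)$ term reaches
$S_x^3$ with x-exponent zero, the one input the integral operators reject.
`index_table()` records such cells as `NA` instead of aborting a batch run.

## Polysaccharide families

Guar gum (a galactomannan) and its hydroxypropyl (HPG), carboxymethyl
(CMG) and carboxymethyl-hydroxypropyl (CMHPG) derivatives are modelled as
repeat-unit families whose edge partitions are linear in the repeat count
$n \ge 1$, e.g. guar gum:

```{r}
family_partition("guar_gum")
```

HPG and CMG share one partition and are treated as two display names for
the same object.  The families are *defined* by these partition formulas:
repeat-unit drawings are not machine-readable input, and the partition fully
determines every quantity the package computes.  Because the counts are
linear in $n$ and the kernels do not depend on $n$, every index is exactly
linear in $n$; `closed_form()` returns slope and intercept as exact
rationals:

```{r}
closed_form(family_partition("guar_gum"), "M1")
closed_form(family_partition("guar_gum"), "AZI")
```

Where published closed-form coefficients disagree with exact rational
summation over the stated partitions (examples: a guar-gum SDD intercept of
5/2 where the partition gives 11/3; AZI slopes printed as 254.125 and
320.315 where the exact values are 16265/64 = 254.140625 and 5125/16 =
320.3125; a CMHPG SDD slope printed as 106.03 where the partition gives 94),
the package pins the exact rationals.  The same policy governs the packaged
carbohydrate index table: `audit_published_indices()` recomputes every cell
from the published edge partitions and reports the twelve cells where the
as-published table differs; both versions ship, and the as-published table
remains the default regression input because it is what the original
property models were fitted to.

## QSPR models

`fit_qspr()` fits one property on one index in three forms — linear
$P = A + B\,TI$, quadratic $P = A + B\,TI + C\,TI^2$, logarithmic
$P = A + B \ln TI$ (natural log) — by ordinary least squares, reporting the
multiple-R convention: $r = \sqrt{r^2} \ge 0$ regardless of slope sign,
$F = (r^2/k)\,/\,((1-r^2)/(n-k-1))$ with $k$ predictors, and $p$ the upper
tail of $F(k,\,n-k-1)$.  `qspr_report()` crosses 5 properties with 7
indices and 3 forms (105 fits).  The molecular-weight models on the
as-published indices reproduce the published correlation strengths
($r \approx 0.999$ for $M_1$ and $M_2$, $0.998$ for $SDD$, $0.993$ for
$AZI$); the boiling-point, melting-point, solubility and density rows are
*not* reproducible from the packaged property and index tables (the data
behind those published fits evidently differed), so the package reports its
own fits for them and the tests assert only internal consistency
($r=\sqrt{r^2}$, $p$ consistent with $F$, quadratic $r^2$ nesting the
linear one).  The published raffinose density of 884.8 g/cm³ is preserved
as data but excluded from density fits by default
(`exclude_anomalous_density`); it is implausible by three orders of
magnitude and would otherwise dominate every density model.

With eight structures, $n - k - 1$ is 6 (linear/logarithmic) or 5
(quadratic): these are descriptive recomputations, not models with
predictive ambitions.

## Synthetic data

Two generators support the tests and are regular package API:

* `random_chemical_graph(n, max_degree, seed)` grows a random spanning tree
  under a degree cap (default 4, the organic valence ceiling) and adds a
  random number of extra edges where the cap allows, giving connected
  graphs with trees, rings and fused rings — the degree profile of
  hydrogen-suppressed organic skeletons.  It emulates nothing about
  element identity, bond order or geometry; passing the dual-route
  equivalence on these graphs certifies the calculus on arbitrary
  partitions with degrees 1–4, not chemical realism.
* `synthetic_qspr_data(n, form, coefficients, noise_sd, seed)` draws the
  index variable uniformly on a positive range (default 1–50, the order of
  magnitude of the small-molecule index values here) and adds Gaussian
  noise to the chosen model form.  Coefficient-recovery tests use 500
  replicates of size 40 at noise SD 2 — large enough that the Monte-Carlo
  standard error separates a real bias from noise, small enough to run in
  seconds — and require noiseless fits to be exact.

Both are deterministic in their seed and restore the session RNG state.

## Limitations

* Indices are degree-based only; distance-based descriptors (Wiener,
  Hosoya) are out of scope.
* SMILES/MOL ingestion (via the suggested ChemmineR/ChemmineOB packages)
  discards bond order and aromaticity by design: degree-based indices
  cannot see them.
* The family closed forms hold for the stated partition formulas at integer
  $n \ge 1$; no claim is made about the chemistry of chain termination at
  other $n$.
* With eight observations the QSPR fits are reproductions, not validated
  predictive models; no cross-validation or multi-descriptor modelling is
  attempted.
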