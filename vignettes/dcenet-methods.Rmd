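---
title: "Differential co-expression across individuals: the methods behind dcenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression across individuals: the methods behind dcenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcenet)
```

## The model

`dcenet` detects genes whose *co-expression neighborhood* changes between
two groups of individuals, each profiled over its own time series. The
central assumption is that co-regulation expresses itself as correlation
*within* an individual's time course, while the timing of the underlying
program (onset, speed) may vary freely between individuals. Any statistic
computed within one individual is invariant to that individual's time
warp; statistics computed after averaging individuals are not.

For genes $g,h$ and individual $i$ with $m$ time points, the Pearson
correlation $r_{ghi}$ is computed over the time-ordered values (spacing
is ignored: correlation does not see the clock, only the ordered pairs).
Its two-sided significance under the null of no correlation uses

$$t = r\sqrt{\frac{m-2}{1-r^2}} \sim t_{m-2},$$

which is why every individual must contribute at least $m = 3$ time
points. The signed significance weight is

$$w_{ghi} = \operatorname{sgn}(r_{ghi})\,(1 - p_{ghi}) \in [-1, 1].$$

A pair is retained ($a_{gh} = 1$) when, in at least one group $G$ with
$n_G$ individuals, at least
$T_G = \max(\lceil 0.25\,n_G\rceil,\ \min(2, n_G),\ 1)$
individuals show a *same-signed* significant ($p < 0.05$) correlation.
With the group-averaged weights $\bar w_X, \bar w_Y$ the score is

$$d_g = \frac{\sum_h a_{gh}\,\lvert \bar w_X(g,h) - \bar w_Y(g,h)\rvert}
             {\sum_h a_{gh}\,\bigl(\lvert \bar w_X(g,h)\rvert + \lvert \bar w_Y(g,h)\rvert\bigr)},
  \qquad d_g \in [0, 1],$$

with $d_g = 0$ when the denominator is zero (no retained, non-trivial
neighborhood — such a gene carries no evidence either way). Per retained
edge, the ratio term reaches 1 exactly when the weaker averaged weight is
zero or of opposite sign to the stronger one; $d_g = 1$ therefore means
the gene's entire retained neighborhood flips or vanishes between groups.

## Design choices in the ambiguous corners

Several details of the procedure admit more than one reading; the package
fixes them as follows.

**Weight function.** $w = \operatorname{sgn}(r)(1-p)$ is used rather than
$w = r$: it is monotone in $|r|$ at fixed $m$, accounts for series
length, and makes the retention rule ($p<0.05$) coincide with
$|w| > 0.95$ — the same cut used for drawing "strong" edges in switching
neighborhoods, so the retained graph and the drawn graph agree. The
weight function is a pluggable argument of `build_individual_network()`;
passing `function(r, p) r` recovers plain correlation averaging.

**Score denominator.** The total-neighborhood normalizer
$\sum_h a_{gh}(|\bar w_X| + |\bar w_Y|)$ is the unique natural choice for
which both boundary facts hold verbatim: equal neighborhoods give exactly
0, and opposite-sign-or-zero neighbors give exactly 1 (a max-based
denominator would allow values above 1).

**Threshold arithmetic.** "At least 25%" rounds up;
the minimum of two individuals applies only where the group has two
($\min(2, n_G)$); and $T_G$ is floored at 1 so that degenerate settings
(`frac = 0`, `min_count = 0`) retain pairs significant in at least one
individual rather than retaining everything unconditionally.

**Sign handling.** The positive and negative significance counts are
tested separately: a pair that is significantly positive in some
individuals and significantly negative in others is *not* consistent
evidence, and the two counts do not pool. This reflects the filter's
purpose — consistent co-expression across individuals — and is symmetric
under global sign flips of a gene.

**Degenerate series.** A gene that is constant within an individual has
no defined correlation; such pairs are set to $r = 0, p = 1, w = 0$
rather than propagating `NaN`. Correlations at exactly $\pm 1$ get
$p = 0$ (limit of the $t$ tail).

**Permutation significance.** The empirical null permutes the group
labels of *whole individuals* (preserving group sizes); shuffling
individual samples would destroy the within-individual time series that
the method is built on. Per-individual networks do not depend on the
labels and are computed once. Null scores are pooled across genes and
permutations: with the conventional 100 permutations a per-gene null
cannot resolve $p < 0.01$, while the pooled null has
$n_{\text{perm}} \times n_{\text{genes}}$ values. P-values use the
add-one form $(1 + \#\{\text{null} \ge d_g\})/(1 + N_{\text{null}})$ so
they are never zero. The trade-off of pooling is that the null mixes
genes with small and large retained neighborhoods; on the package's null
cohorts the resulting p-values test as (slightly super-) uniform.

**Determinism.** All rankings break score ties by lexicographic gene id;
every stochastic function requires an explicit seed and restores the RNG
state afterwards.

## Parameters and defaults

| parameter | default | role |
|---|---|---|
| `p_cut` | 0.05 | per-individual significance for the prefilter; deliberately liberal, meant to discard only clearly uninteresting links |
| `frac` | 0.25 | minimum fraction of a group's individuals with consistent significance |
| `min_count` | 2 | floor on that count where the group is large enough |
| `n_perm` | 100 | group-label permutations for score significance |
| enrichment permutations | 10000 | gene-label permutations in `enrichment_permutation()` |
| `beta` | 6 | soft-threshold power of the baseline connectivity ranking (conventional for signed-magnitude adjacencies; the comparison strategies are analogs of the published average/concatenate/individual-correlation routes, not clones of any particular package) |
| `diff_fraction` | 0.005 | fraction of genes selected as a switching neighborhood ("top 0.5%") |
| `edge_cut` | 0.95 | minimum $|\bar w|$ for a drawn edge, equivalent to $p < 0.05$ under the default weight |
| `top_sizes` | 200 | top-list size for reproducibility summaries |

## The synthetic cohort generator

`synthetic_config()` / `simulate_cohort()` generate the study conditions
used throughout the tests: two groups of `n_individuals = 6`, a common
nominal grid of `m = 8` time points on $[0,1]$, and `n_genes = 300` genes
organised in three modules of 100. Gene $g$ of module $M$ in individual
$i$ at nominal time $t$ is

$$x = \lambda_g\, f_M(s_i t + o_i) + \varepsilon,\qquad
  s_i = e^{\mathcal N(0, 0.3)},\quad o_i \sim \mathcal N(0, 0.15),\quad
  \varepsilon \sim \mathcal N(0, 0.3),$$

with loadings $\lambda_g \sim \mathcal N(1, 0.2)$ and a fixed trajectory
library (sigmoid, pulse, down–up–down oscillation), scaled to
approximately zero mean and unit amplitude so that module pairs correlate
at $|r| > 0.8$ within an individual at the default noise level. Warping
happens in latent time while the nominal grid is shared, so the
group-average baseline is well defined on every cohort.

Choices worth making explicit:

* **Fully structured background.** By default every gene belongs to a
  module. The cohorts emulate expression matrices *after* the usual
  non-specific variance filter, which removes unstructured genes (their
  variance here, $0.09$, is about six-fold below a module gene's).
  Setting `module_sizes` to sum below `n_genes` leaves the remainder as
  pure observation noise; the test suite exercises that regime too. This
  matters for interpretation: genes with no consistent structure in
  either group that sneak past the prefilter in small cohorts receive
  large score ratios, so on a background-heavy cohort the ranking's
  contrast is between decoupled genes and spurious-edge noise genes
  rather than between decoupled and coupled genes.
* **Decoupling = loss of phase relation.** A decoupled gene keeps smooth
  dynamics in group Y (a sinusoid with gene-specific frequency) but its
  phase is redrawn *per individual*, so it carries no reproducible
  relation to the shared program. A single fixed alternative trajectory
  would itself be consistently co-expressed across group-Y individuals
  and would not be "decoupled" in any useful sense.
* **Switch gene.** With `switch_gene = TRUE` one gene follows module 1's
  trajectory in group X and module 2's in group Y, planting the
  neighborhood-switching pattern that `switching_neighborhood()` is
  designed to display.
* **What averaging does and does not lose here.** With white observation
  noise, averaging $n$ individuals cuts the noise variance by $n$, so the
  group-average route loses correlation relative to the within-individual
  route only where the warp attenuates the shared trajectory's variance
  by more than $n$-fold. At the default warp this holds for the
  oscillatory module (whose phase at late times spreads by a large
  fraction of a cycle across individuals) but not for monotone dynamics,
  which survive averaging essentially intact. The decisive degradation
  the score exploits is therefore on the *decoupled* genes — their
  group-Y association is gone for every method, but only the
  individual-correlation route measures the group-X association reliably
  enough at small $n$ to expose the difference. Passing the recovery
  tests consequently shows robustness to timing heterogeneity and
  decoupling, not superiority on data whose structure averaging preserves.
* **What the generator does not emulate:** probe-level artefacts,
  count-type (sequencing) noise, missing values, unequal time grids
  between individuals, correlated noise between genes outside modules,
  and group differences in mean expression without co-expression change.

## Evaluation harnesses

`subsample_reproducibility()` draws $2n$ individuals per group without
replacement and splits them into two *disjoint* sub-cohorts — overlapping
draws would mechanically inflate the overlap of the two rankings. Each
repetition redraws independently. `top_overlap()` is the relative top-$k$
intersection, with chance level $k/G$. `enrichment_permutation()` tests
the mean of an external gene property over the top-$k$ against gene-label
permutations, one-sided (excess effect), with the same add-one rule;
genes without a property value must be dropped before ranking, and a
constant property yields $p = 1$ with a warning.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at desk scale, chosen so the
whole suite completes in well under a minute while keeping the Monte
Carlo assertions sharp: oracle equivalence on 100 random instances of up
to 10 genes and 4 individuals per group ($m=5$, tolerance $10^{-10}$
against a scalar nested-loop recomputation); correlation-test calibration
on 10,000 independent Gaussian pairs at $m = 6$; permutation-null
calibration on ten 60-gene null cohorts at 100 permutations each;
planted-signal recovery on ten default 300-gene cohorts (with the
average-profile baseline ranked on identical data); chance-overlap
checks on a 2,000-gene cohort over 100 subsample pairs; and a 1,000-gene
switch-gene cohort driven through the command-line interface.

## Known limitations

* Pearson correlation only; rank-based or spacing-aware association
  measures are not implemented (the weight function is pluggable, the
  correlation is not).
* Short series ($m < 5$) make the $t$ approximation coarse and the
  prefilter either porous or starved; the method is designed for
  $m \approx 5$–10.
* The pooled permutation null ignores between-gene differences in
  neighborhood size; p-values are calibrated marginally, not per gene.
* With very small groups ($n_G = 2$–3) the consistency threshold bottoms
  out at 2 individuals and spurious pairs pass more easily; scores of
  genes with tiny retained neighborhoods should be read together with
  their permutation p-values.
* Missing values are rejected, not imputed.
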