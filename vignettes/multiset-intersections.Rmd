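---
title: "Exact inference for multi-set intersections: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact inference for multi-set intersections: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msetest)
```

## The statistical model

`msetest` answers one question: if $t$ sets of fixed sizes $s_1,\dots,s_t$
are each an independent uniform sample (without replacement) from a finite
background population of $n$ elements, how surprising is it that all of them
share at least $x$ elements?

For $t = 2$ the intersection size $X$ follows the classical hypergeometric
law, $P(X = x) = \binom{s_1}{x}\binom{n-s_1}{s_2-x}/\binom{n}{s_2}$ — the
Fisher-type overlap test. For $t \ge 3$ the density is a nested sum over
every intermediate overlap that is compatible with the final one: the first
two sets share $j$ elements with hypergeometric probability, a third set of
size $s_3$ intersects that $j$-subset in $k \le j$ elements with probability
$\mathrm{dhyper}(k;\, j,\, n-j,\, s_3)$, and so on until the last set. Only
the final overlap $x$ is observed; all intermediate sizes are integrated
out. The one-tailed significance is the inclusive upper tail
$P(X \ge x) = \sum_{i=x}^{m} P(X = i)$ with $m = \min_i s_i$, the largest
achievable overlap. A depletion (lower-tail) version is available via
`pmset(..., lower.tail = TRUE)` and `mset_exact_test(..., alternative =
"less")`, but enrichment is the default and the mode used everywhere else in
the package.

Two descriptive statistics accompany the tail probability. The expected
intersection size under independence is $E[X] = n\prod_i (s_i/n)$, and fold
enrichment is the observed-to-expected ratio $\mathrm{FE} = x / E[X]$, zero
exactly when $x = 0$. Note that $\mathrm{FE}$ compares fractions of the
background, so it is only defined when every $s_i > 0$ and $x \le m$.

### Key modelling assumptions

* **Independent, uniform sampling.** Each set is an unbiased draw from the
  same background. The simulation module (below) quantifies what happens
  when this fails.
* **Total (non-exclusive) overlap.** The tested quantity for a combination
  of sets is the number of elements common to *all* of them, regardless of
  membership in sets outside the combination. This is the quantity the null
  model describes; Venn-style *exclusive* region counts are available
  (`exclusive_region_counts()`) for display but carry no test.
* **The background matters.** Every probability is conditional on $n$;
  supplying a too-small or too-large universe silently corrupts all
  p-values. For that reason `mset_test()` has no default background, and
  when an explicit universe is given, set members outside it raise an error
  unless deliberately dropped.

## The forward algorithm

Evaluated literally, the nested sum has one summation index per additional
set and its cost grows exponentially with $t$. The package factorizes it as
a forward dynamic-programming pass, the same device used for hidden Markov
model likelihoods: the state after processing $i$ sets is the distribution
of the running overlap, a vector indexed by overlap size, and each new set
updates it through the hypergeometric kernel
$f_{i+1}(k) = \sum_{j \ge k} f_i(j)\,\mathrm{dhyper}(k;\, j,\, n-j,\,
s_{i+1})$. Each update touches at most $(m+1)^2$ state pairs, so the whole
pmf costs $O(t\,m^2)$ kernel evaluations — linear in the number of sets. A
unit test asserts this operation count directly (each extra equal-sized set
adds exactly $(m+1)^2$ kernel evaluations), rather than timing wall clocks.

Two implementation choices matter:

* **Processing order.** The result is invariant under permutation of the
  sets (a tested property), so the sets are processed in decreasing size
  order: the state support is bounded by the smallest size seen so far, and
  descending order shrinks the table as early as possible.
* **Exact truncation.** The running overlap never grows, so when only the
  tail from $x$ is needed the state can be truncated below $x$ without
  error. The full-distribution pass (`x0 = 0`) is used wherever several
  tails of the same configuration are needed.

### Oracles

Because the forward pass is the piece of machinery everything else rests on,
the package ships two independent reference implementations used by the test
suite (and usable by anyone auditing a result):

* `dmset_naive()` — the nested sums evaluated by direct recursion,
  re-computing every inner sum for each outer index. Exponential in $t$,
  supported for 2–6 sets.
* `dmset_exhaustive()` — literal enumeration of every configuration of
  subsets of the stated sizes (bitmask representation, exact integer
  counting), feasible for 2–3 sets over tiny backgrounds.

The suite checks forward = naive (to $10^{-10}$ relative, $t \le 5$),
forward = exhaustive ($t = 3$, $n \le 9$), normalization of the pmf to 1
($10^{-9}$), exact agreement with `dhyper`/`phyper` at $t = 2$, tail
monotonicity, and agreement with $10^5$ uniform Monte-Carlo draws at total
variation below 0.01.

## Numerical policy

Binomial coefficients of large arguments overflow doubles long before the
probabilities themselves become extreme, so **every accumulation happens in
natural-log space** (log-sum-exp), with `lchoose`/`dhyper(log = TRUE)`
supplying log-scale terms. Working precision is 64-bit floating point
throughout the main path; the oracles may use exact integer/rational
arithmetic.

Log-space alone is not enough at the output boundary: a seven-set
intersection of realistically sized gene sets can have a tail probability
around $10^{-95}$, and six-set consensus overlaps fall below $10^{-300}$ —
the smallest positive double is about $5\times10^{-324}$. Every result
therefore carries a `log10` companion (`log10.p`, `log10_p_adjusted`,
`log10.P` in the summary table) that stays finite whenever the tail is
mathematically positive, and the summary formatter prints scientific
notation computed *from the log value*, so `1.04e-409` appears as such
rather than as `0`. Multiple-testing adjustment is likewise performed on the
log10 scale: Bonferroni adds $\log_{10} M$ (capped at 0) and
Benjamini–Hochberg runs its step-up on log-scale candidates, which the tests
cross-check against `stats::p.adjust` on inputs where both are computable.

Degenerate inputs follow one rule: an observed overlap above $m$ is not an
error for probability functions (density 0, upper tail 0) because callers
enumerate combinations mechanically, but fold enrichment — a statement about
an actually observed overlap — rejects it.

## Enumeration and the multiple-testing family

`mset_test()` enumerates all $2^t - 1$ non-empty combinations (refusing
$t > 30$ rather than truncating). Degree-1 records exist for display and
carry no statistics. The adjustment family is always the complete set of
$M = 2^t - t - 1$ combinations of degree $\ge 2$ — even when `min_degree`
hides rows from the output — so displayed p-values do not depend on display
filters. For seven sets $M = 120$.

One test deserves a note. A natural sanity check is that raw p-values are
"uniform under the null", but the exact test is discrete: its upper-tail
p-values are *super-uniform* ($P(p \le \alpha) \le \alpha$), and a literal
Kolmogorov–Smirnov test against $U(0,1)$ would reject with any sufficiently
large simulation. The calibration test therefore checks (a) the simulated
overlap counts against the exact pmf by chi-square goodness of fit and
(b) super-uniformity of the p-values over a grid of thresholds within
Monte-Carlo error — the operationally meaningful property (the test never
anti-conservatively exceeds its nominal level under the null).

## The weighted-sampling simulator

`fpr_experiment()` probes robustness to the independence assumption. In each
replicate, one set per entry of `set_sizes` is drawn from a population of
$n$ elements in which the first `n_pref` elements carry sampling weight
$w \ge 1$ and the rest weight 1; the one-tailed exact p of the overlap among
all sets is computed and the false-positive rate is the fraction of
replicates with $p < \alpha$ (strictly; `alpha = 1` is interpreted as
"count every replicate", since a level-1 test always rejects). Defaults are
the study design the simulator emulates: sizes 200, 300, 400, `n_pref =
100`, $\alpha = 0.05$, 1000 replicates.

* **Sampling scheme.** "Weight $w$" means sequential draws without
  replacement, each draw proportional to the weights of the elements still
  available. The implementation uses the exponential-key construction (take
  the $k$ smallest of $\mathrm{Exp}(1)/w_i$ keys), which is exactly
  equivalent to the sequential scheme and vectorises; the equivalence is
  verified in the tests against a brute-force enumeration of the sequential
  draw probabilities at small $n$, and the $w = 1$ case against uniform
  marginal inclusion by chi-square.
* **One pmf per configuration.** The null tail depends on the data only
  through the observed overlap, so the full distribution is computed once
  per $(\text{sizes}, n)$ and each replicate costs a table lookup. This is
  what makes 1000-replicate cells run in seconds.
* **Reproducibility.** The experiment seed generates one sub-seed per
  replicate upfront; identical seeds give identical rates, and replicates
  are order-independent. The returned 95% interval is the Wilson score
  interval.

What these simulations emulate — and what they do not: elements differ only
in a two-level sampling weight, sets share one background, and set sizes are
fixed by design. Real gene sets add structure this ignores (correlated
curation, varying annotation depth, overlapping ontologies), so a clean FPR
here shows the method behaves at its stated level under the modelled
departure from independence, not under every real-world dependence.

## The synthetic collection generator

`make_fixture_collection()` builds collections with *exactly* planted total
overlaps: plants are processed in decreasing degree, each receiving a block
of fresh elements after crediting blocks already placed by superset
combinations, and infeasible requests fail with the violated budget. When
any plant is present, the remaining members of each set are filled from
elements used by no other set — independent uniform fills would collide and
perturb the planted counts — so exactness is bought by giving up marginal
uniformity of the fills. With no plants the sets are plain independent
uniform draws. Tests and demos use it both ways.

## Visualization choices

All four layouts encode significance as colour intensity in
$-\log_{10}(\text{adjusted } p)$, **capped** at a configurable ceiling
(default 10): without a cap, a $10^{-300}$ intersection would flatten every
other signal out of the palette; records without a test (degree 1) render
neutral grey. Matrix and circular layouts draw bars exactly proportional to
observed counts (the plot functions invisibly return their geometry so the
proportionality is testable), columns/sectors ordered by the chosen sort key
with barcode order breaking ties, circular sectors starting at 12 o'clock
and running clockwise. The network layout is a seeded Fruchterman–Reingold
embedding (node area proportional to log set size, edge width to overlap,
edge colour to significance), so a fixed seed gives identical coordinates.
Rendering is deterministic: drawing the same specification twice produces
byte-identical vector output.

## Problem sizes used in the checks

The test-suite simulations are sized to be decisive yet quick: $10^5$ draws
for distributional agreement (total variation tolerance 0.01), 500
collections for p-value calibration, 400–1000 replicates per
false-positive-rate cell (bounds stated as three binomial standard errors),
and oracle comparisons on backgrounds small enough for exact enumeration.
The acceptance script runs the full 1000-replicate cells of the simulation
design.

## Known limitations

* The main path is 64-bit floating point; results are accurate to roughly
  $10^{-10}$ relative against exact arithmetic on test configurations, but
  no arbitrary-precision mode is offered.
* Enumeration of all combinations is $2^t$; collections beyond 30 sets are
  refused by design (single combinations of any size remain testable via
  `mset_exact_test`).
* The model conditions on set sizes; it does not model uncertainty in set
  membership or element-level weights.
* Exclusive-region counts are display-only; no exact test is attached to
  Venn cells.
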