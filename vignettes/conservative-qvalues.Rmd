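---
title: "Conservative adjustment of q-values: model, guarantees and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservative adjustment of q-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqvalue)
```

## The problem

After testing $m$ genes simultaneously, calls at a threshold $t$ on a test
score $T$ split into the classical multiple-testing counts: $R$ genes called
positive, of which $V$ are false positives, so the realized false discovery
proportion is $V/R$. The q-value estimates the FDR at each observed
threshold by

$$q(t) \;=\; \frac{\hat\pi_0\,\hat\alpha(t)}{\hat\gamma(t)},$$

where $\hat\pi_0$ estimates the true-null proportion,
$\hat\alpha(t) = \#\{T^0 \ge t\}/r$ is the permutation p-value computed from
a pool of $r$ permuted scores, and $\hat\gamma(t) = \#\{T \ge t\}/m$ is the
fraction of observed scores at or above $t$. All three components are random;
each can undershoot its target, and the ratio then understates the true FDR

$$\tilde q(t) \;=\; \frac{\pi_0\,\alpha(t)}{\gamma(t)},
\qquad \alpha(t) = \Pr(T \ge t \mid H_0),\;
\gamma(t) = \Pr(T \ge t).$$

An underestimated FDR is the expensive direction of error: it sends genes to
validation that will not replicate. This package provides, next to $q(t)$, a
$100(1-a)\%$ *conservative adjustment* $\hat q_c(t)$ with

$$\Pr\!\left[\hat q_c(t) \ge \tilde q(t)\right] \ge 1 - a$$

at each observed threshold.

## The adjustment

Both $\hat\alpha$ and $\hat\gamma$ are rank-based quantile estimators — at
the $i$-th order statistic they equal $(r-i+1)/r$ and $(m-i+1)/m$ — and the
exceedance counts behind them are binomial under independence. The
adjustment replaces each component by a one-sided confidence limit:

* $\hat\alpha_c(t)$: the smallest $u$ with
  $\Pr[\mathrm{Bin}(r, u) \le k] \le a_1$, i.e. the $(1-a_1)$ quantile of
  $\mathrm{Beta}(k+1,\, r-k)$, where $k = \#\{T^0 \ge t\}$;
* $\hat\gamma_c(t)$: the largest $l$ with
  $\Pr[\mathrm{Bin}(m, l) \ge j] \le a_2$, i.e. the $a_2$ quantile of
  $\mathrm{Beta}(j,\, m-j+1)$, where $j = \#\{T \ge t\}$;
* $\hat\pi_{0c}$: a conservative point estimate (no budget spent,
  $a_0 = 0$; see below).

These are the classical one-sided Clopper–Pearson limits, expressible
through the regularized incomplete beta function; they are exactly
conservative with no assumption on the score distribution. The tests verify
them against a brute-force binomial-tail search on a $10^{-6}$ grid, and
verify the coverage claim itself by direct summation of the binomial pmf
over all outcomes — not by simulation — for a grid of truth values.

If the component mis-coverages satisfy the **multiplicative budget**

$$(1-a_0)(1-a_1)(1-a_2) \;\ge\; 1-a,$$

then $\hat q_c = \hat\pi_{0c}\hat\alpha_c/\hat\gamma_c$ meets the coverage
requirement: conditioning on $\hat\pi_{0c} \ge \pi_0$, then on
$\hat\alpha_c \ge \alpha$, and finally using
$\Pr[\hat\gamma_c \le \gamma] \ge 1-a_2$ peels off the three factors, since
each conditioning event can only enlarge the ratio (for any $X \ge 1$ and
constant $c$, $\{Y \ge c\} \subseteq \{XY \ge c\}$). `make_budget()` splits
$a$ evenly on the multiplicative scale: each of the $c$ active components
gets $1-(1-a)^{1/c}$, so `make_budget(0.05)` gives
$a_1 = a_2 = 1-\sqrt{0.95}$ and the constraint holds with equality.

Only an upper confidence limit is offered. A lower limit would require an
anti-conservative handle on $\pi_0$, which conservative $\pi_0$ estimation
deliberately forgoes.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `a` | overall mis-coverage of $\hat q_c$ | 0.05 | conventional 95% confidence |
| `a0` | budget spent on $\pi_0$ | 0 (fixed) | $\pi_0$ estimators are already conservative; spending budget here wastes it |
| `a1`, `a2` | budget on $\hat\alpha$, $\hat\gamma$ | $1-\sqrt{1-a}$ each | even multiplicative split; with theoretical p-values `a1 = 0` and `a2 = a` |
| `pi0` | `"fixed"` (1.0), `"storey"` ($\lambda = 0.5$), `"external"` | `"fixed"` | 1.0 strictly satisfies $\Pr(\hat\pi_{0c} \ge \pi_0) = 1$; Storey is the practical choice; external admits convex-density estimators (e.g. convest) computed elsewhere — that algorithm is not re-implemented here |
| `permutations` | `"exhaustive"` or `"sampled"` | exhaustive | all $\binom{n_1+n_2}{n_1}$ balanced relabelings, halved to $\binom{2g}{g}/2$ when $n_1 = n_2 = g$ since group names are interchangeable for $|t|$ (126 for 5+5) |
| `n_random` | sampled relabelings | 1000 | drawn uniformly **with replacement** (the identity split may recur); how application-scale permutations were drawn is not specified by convention, so the simpler scheme is used and recorded |
| `include_observed` | observed scores belong to the pool | `TRUE` | the observed data are the identity relabeling; inclusion guarantees $k \ge 1$, $j \ge 1$ at every observed threshold, so no p-value or q-value is ever 0 |
| `cap` | exhaustive-enumeration refusal point | 20000 | above it the engine errors and tells the caller to sample, rather than silently degrading |

## Numerical and degenerate-input choices

* **Two-sided testing.** Scores are $|t|$ (pooled-variance two-sample t), so
  exceedance sets are one-sided in $|T|$ and differential expression in
  either direction counts; the simulation design is symmetric.
* **Zero pooled variance.** Equal means give score 0; unequal means would
  give $\pm\infty$ and are mapped to the maximum finite score in the matrix
  plus 1, with a warning. Ranks stay meaningful and no NaN propagates.
* **Ties.** Exceedance counts are inclusive ($\ge$), matching the indicator
  definition of the estimators; tied scores receive identical q-values.
* **Monotonization.** The defining ratio need not be monotone in $t$. Both
  $q$ and $q_c$ are made nonincreasing in the score by a running minimum
  taken from the least significant threshold downward — the universal
  q-value convention ("the smallest estimated FDR at which this gene is
  called"). Per-threshold coverage survives: the running minimum can only
  substitute the bound of a less significant threshold, whose target
  $\tilde q$ is no smaller, and the harness checks the composite empirically.
* **Clipping.** To $[0,1]$, applied after monotonization.
* **$\hat\gamma_c = 0$** can only arise at unobserved thresholds ($j = 0$);
  the ratio is then defined as 1, enforcing
  $\Pr[\hat\gamma_c > 0] = 1$ structurally.
* **Zero budget** is an exact pass-through: a component with level 0 uses
  its point estimate, so `a = 0` reproduces the unadjusted q-values
  bit-for-bit (tested).
* **Missing values** are rejected at input, never imputed.

## What the simulation harness emulates

`generate_scenario()` draws the stated Gaussian world: $m$ genes, two groups
of $n_1 = n_2 = 5$ samples; null genes $N(0,1)$ in both groups, DE genes
$N(0,1)$ vs $N(\Delta,1)$, with $\texttt{round}(m(1-\pi_0))$ DE genes. Under
this model the |t| score of a null gene is central $t_{n_1+n_2-2}$ and of a
DE gene noncentral with $\mathrm{ncp} = \Delta\sqrt{n_1 n_2/(n_1+n_2)}$, so
the true FDR is available in closed form:

$$\tilde q(t) = \frac{\pi_0 S_0(t)}{\pi_0 S_0(t) + (1-\pi_0) S_1(t)},$$

with $S_0$, $S_1$ the two-sided tail probabilities (`theoretical_fdr()`;
checked against numerical quadrature of the densities, and against the mean
realized FDP over replicates). `run_coverage_experiment()` repeats the whole
permutation pipeline and reports (i) the fraction of replicates in which the
plain q-value dips below $\tilde q$ where $\tilde q < 0.05$ — the
underestimation phenomenon — and (ii) the fraction in which
$\hat q_c \ge \tilde q$ at *every* observed threshold, which the theorem
puts at $\ge 1-a$. Inside the harness the plain q-values use Storey's
$\hat\pi_0$ (the practical pipeline whose underestimation is being
demonstrated) while the adjusted q-values use $\hat\pi_{0c} = 1$, isolating
the adjustment's guarantee from $\pi_0$ estimation error.

Default scale is $m = 2000$ genes and 20 replicates, which reproduces the
qualitative findings in about two seconds on one CPU; the reference scenario
grid ($m = 10{,}000$, 100 replicates, $\Delta \in \{1,2\}$, DE proportion
10–20%) is reachable by passing those values explicitly.

What a green harness does **not** establish: the generator draws independent
genes with unit variance and a pure mean shift. Real expression data are
correlated across genes, heteroscedastic and heavy-tailed. The binomial
model behind the confidence limits likewise treats pool entries as
independent draws, which a pooled null shared across genes violates; the
adjustment is implemented as designed, and this caveat is inherited from the
pooled-permutation design itself. Coverage statements are per-threshold
(combined over observed thresholds empirically), not simultaneous confidence
bands.

## Design choices where the design was open

* **Which incomplete-beta bound.** Any one-sided bound with the claimed
  coverage works; the classical Clopper–Pearson form is adopted because its
  coverage is exact and provable by finite summation, which the test suite
  does. A rank-shifted variant would change the bounds by $O(1/r)$ without
  changing the guarantee.
* **Whether to monotonize $q_c$.** Displayed q-value curves are
  conventionally monotone; both columns are monotonized so each is a valid
  FDR curve, and the choice is validated by the coverage experiment.
* **$\pi_0$ inside the package.** A convex decreasing-density estimator is a
  different algorithm with its own literature; rather than re-implement it,
  the package ships a strictly conservative default (fixed 1.0), Storey's
  estimator for practice, and an injection path for external estimates. For
  small $m$, Storey's estimate can undershoot $\pi_0$ and erode coverage —
  flagged here, not resolved.
* **Sampled relabelings with replacement**, identity appended when absent,
  so observed thresholds always have positive exceedance counts.

## Limitations

Over-conservatism is the price of the guarantee: with small pools or few
genes the one-sided limits are wide, and adjusted q-values near the top of
the ranking can be several-fold larger than the point estimates (that gap is
informative — it measures how fragile the low q-values are). Only two-group
designs with the pooled-variance t (permutation path) or caller-supplied
p-values (theoretical path) are supported; paired designs, covariates and
other statistics are out of scope, as are local FDR and
Benjamini–Hochberg-style adjusted p-values.
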