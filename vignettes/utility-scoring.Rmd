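---
title: "Multi-attribute utility scoring of paired biostimulant trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-attribute utility scoring of paired biostimulant trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoiabs)
```

## The scoring model

`apoiabs` evaluates a crop biostimulant from paired field observations:
each indicator is measured in a treated field and in a neighbouring
untreated control selected so that the product application is the sole
contrasting feature.  The design is side-by-side commercial fields, not
randomized replicated plots, so the package makes no design-based
inference; it scores observed contrasts.

Each indicator $i$ produces two calculated indices from the
replicate-summarized arm levels $c_i$ (control) and $t_i$ (treatment):

* the **impact index** $\Delta_i = 100\,(t_i - c_i)/c_i$, the percent
  change from control to treatment, and
* the **technical performance index**, the treatment level $t_i$
  itself, judged against agronomic benchmarks.

Both are mapped to a utility $u \in [0,1]$ through the indicator's
*correspondence table*, a set of (calculated index, utility) knots, via
a monotone curve $U_i(\cdot)$.  The system's central axiom is the
**baseline**: $U_i(\Delta = 0) = 0.7$ for every impact curve (zero
change, no impact) and $U_i(b_i) = 0.7$ for every performance curve,
where $b_i$ is the indicator's technical-suitability level.  The
baseline is enforced *by construction* — the anchor knot is injected
into the table before fitting — so it holds to machine precision, not
merely approximately.

Theme indices are unweighted arithmetic means of member utilities over
the indicators actually scored; the overall impact and performance
indices are pooled means over the full scored set.  Pooled means and
means of theme means differ whenever theme sizes are unequal (they are:
9/9/5/6/10), so both are reported, with the pooled value as the
headline figure because the system is defined over the whole indicator
set.  Indicators are equally weighted throughout; the method specifies
no weights.

## The default indicator system

`default_config()` ships five analytical themes and 39 indicators:
crop development and production (9), soil chemistry (9), soil physics
(5), soil biology (6), and plant health (10).  Named indicators follow
the published system structure — e.g. β-glycosidase with its
explanatory variable bounded at 0–200 mg p-nitrophenol·kg soil⁻¹·h⁻¹,
and soil compaction with *negative* direction (a reduction is
favourable).  Two deliberate openings remain in the shipped defaults:

* **Plant health** is structurally complete but inert: its ten
  indicators are placeholders (`plant_health_01` … `plant_health_10`)
  because their identities are deployment-specific; they score normally
  once renamed and calibrated.
* **Correspondence knots** other than the anchoring convention are
  calibration defaults, not published facts: impact tables span
  −50 % … +50 % change with utilities 0.20 … 1.00 through the
  (0, 0.7) anchor, and performance tables span each indicator's
  explanatory range through the ($b_i$, 0.7) anchor.  They encode a
  reasonable marginal-utility shape for field variables and are meant
  to be overridden per deployment via the YAML configuration
  (`write_config()` / `load_config()`).

`validate_calibration()` runs the two calibration checks the method
prescribes per indicator: the *probability test* (explanatory
thresholds bracket the performance table's domain; declared direction
agrees with the utility monotonicity) and the *sensitivity test*
(anchor available; nonzero utility amplitude over the table).  Findings
are returned as data, not raised, so a partially calibrated system can
still be inspected.

## Numerical choices

**Curve fitting.**  The default `fit = "interpolate"` is monotone
piecewise-linear interpolation through the knots — the unique
assumption-free monotone curve through the correspondence structure; it
reproduces every knot exactly.  `fit = "least-squares"` fits a
polynomial (default cubic, capped at #knots − 1) in the shifted basis
$(x - x_0)^k$ with no intercept, which absorbs the anchor constraint
exactly while minimizing squared knot error; it exists for parity
experiments with externally fitted curve equations and does *not*
guarantee monotonicity between knots.

**Extrapolation.**  Inputs outside the explanatory thresholds take the
endpoint utility (clamping); utilities are additionally clamped to
[0, 1].  Utility curves terminate at their thresholds, and clamping is
the only bounded, monotone extension.

**Monotonicity tolerance** is 1e-9 absolute throughout (calibration
checks and property tests); the anchor is checked at 1e-9 and holds to
~1e-16 in practice.

**Zero control.**  A zero control level makes percent change
undefined.  The engine refuses to compute it and records a flag rather
than substituting an epsilon denominator, which would manufacture
arbitrarily large impact.  Performance is still scored.

**Replicate summary** is the arithmetic mean per arm; the median is
available for outlier-prone profiles (penetrometer readings).  Units
are declared once per indicator and checked by string equality — no
conversion engine, by design.

**Correlations.**  `pearson_matrix()` uses pairwise-complete
observations, the exact $t = r\sqrt{(n-2)/(1-r^2)}$ two-sided test,
and flags pairs with fewer than 3 complete cases or a constant column.
No multiple-testing correction is applied across the matrix — the
method reports raw α = 0.05 significance — and the result object says
so in its `note`.  For numerically perfect correlations the p-value
underflows and is floored at the smallest positive double.

**PCA.**  `pca_kaiser()` works on the correlation matrix (columns
standardized), computed via the singular values of the standardized
data matrix for numerical stability; eigenvalues therefore sum to the
number of columns and each variance fraction is $\lambda/k$.  The
Kaiser criterion retains components with $\lambda > 1$ *strictly*; a
tie at exactly 1.0 is excluded (it carries no more variance than a
single standardized variable).  Missing values are handled listwise by
default or by flagged column-mean imputation.

## What the synthetic generator emulates — and what it does not

`generate_trials()` draws replicate values per farm, indicator and arm
with treatment mean $\mu_c(1 + e)$ for planted multiplicative effect
$e$.  Noise is lognormal by default — field measurements here are
positive-valued — parameterized so the replicate *expectation equals
the arm mean exactly* ($\sigma^2_{\log} = \log(1 + \mathrm{CV}^2)$,
mean-corrected), which makes the planted percent change recoverable
without bias as noise vanishes.  Generation is bit-reproducible under
the spec seed.

The demonstration preset `demo_spec()` mirrors the reference-trial
layout: eight farms (three corn, two soybean, two cotton, one
sugarcane), three replicates per arm, 10 % CV, plant health
unmeasured, and beneficial effects of 12–30 % magnitude (sign-flipped
for negative-direction indicators) chosen so theme impact indices land
in the 0.75–0.85 band.  It is labelled illustrative: it demonstrates
pipeline behaviour at realistic magnitudes and does not reproduce any
field campaign.

The generator does **not** emulate spatial field heterogeneity,
between-farm variance components, measurement censoring, correlated
errors across indicators, or microbiome count data.  Passing tests
therefore establish the *engine's* correctness (anchoring, direction
handling, clamping, aggregation arithmetic, recovery of planted
effects), not the field validity of any particular calibration.

## Validation strategy and problem sizes

The test suite checks each stage against independent oracles:
piecewise-linear evaluation against explicit segment equations (1e-12);
Pearson $r$/$p$ against the covariance/t-statistic formulas and
`cor.test` (1e-10); PCA eigenvalues against a direct
eigendecomposition of the explicitly formed correlation matrix and
against `prcomp` (1e-10); eigenvalue conservation at 1e-9.  Bound and
monotonicity properties run over 10⁵ randomized evaluations across 100
randomly generated calibrated curves.  Effect recovery uses 1000
regenerated trials at CV = 0.05 for the ±1 % Monte-Carlo check and an
effect ladder (−20 %, 0, +20 %) for monotone utility response; these
sizes give Monte-Carlo standard errors several times smaller than the
tolerances they are checked against while keeping the suite quick on a
single CPU.

## Known limitations

* Correspondence tables beyond the anchoring convention are
  package-chosen defaults; results on real data are only as meaningful
  as the per-deployment calibration.
* Percent-change impact scoring is undefined at zero control levels
  and asymmetric around zero (a +50 % change and a −33 % change return
  to the same level); the correspondence tables, not the index, must
  encode any desired symmetry.
* The least-squares curve mode can be locally non-monotone between
  knots; the interpolating default cannot.
* With few case studies (8 farms), the cross-case correlation matrix
  is rank-deficient and PCA eigenvalues beyond rank
  $\min(n-1, k)$ are exactly zero; significance tests at $n = 8$ have
  limited power and no multiplicity control.
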