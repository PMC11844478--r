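---
title: "Inferring the shape of a bivariate genetic relationship from bin-pair genetic correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the shape of a bivariate genetic relationship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgshape)
```

## The problem and the model

Global genetic correlations summarise the relationship between the genetic
components of two traits with a single number, and therefore assume that the
relationship is linear. Many epidemiological relationships are not: both low
and high body-mass index associate with depression, and both short and long
sleep duration do. `rgshape` implements a summary-statistic method for
estimating the *shape* of such a relationship.

Each trait is modelled as the sum of an additive genetic and an
environmental component,

$$ x = a_x + e_x, \qquad y = a_y + e_y, $$

and the estimand is the curve $f$ in $\mathrm{E}[a_y] = f(a_x)$, with $x$
continuous and $y$ binary, ordinal or continuous. The direction of the
equation is not a causal commitment; $f$ describes how the expectation of
$y$'s genetic component varies along $x$'s.

The method proceeds in four stages:

1. **Binning.** The observed trait $x$ is cut into $K$ quantile bins
   (`bin_scheme()` + `assign_bins()`), or fixed-value bins for categorical
   measures such as hours of sleep (`value_bins()`). Every pair of bins
   defines a case/control contrast with the *lower* bin as the case group
   and the higher bin as the control group; $K$ bins give $\binom{K}{2}$
   contrasts (435 for the 30-bin design). Each bin is represented by the
   median of its members' $x$ values, and $d_x$ is the difference of the
   two representative values.
2. **Genetic correlations.** A case/control GWAS of each contrast is run
   externally (e.g. a linear mixed model on biobank genotypes) and its
   genetic correlation $r_g$ with trait $y$ estimated from summary
   statistics (e.g. LD-score regression). `rgshape` *consumes* the
   resulting table (`read_rg_table()`); for validation it can also produce
   one internally from simulated cohorts (`sim_rg_table()`).
3. **Trigonometric transform.** Each correlation is converted to the acute
   angle of a right triangle and then, via the tangent, to an estimated
   distance on $y$'s liability scale (`transform_rg()`):
   $$ \theta = 90 - \arccos(r_g / d_x)\,\tfrac{180}{\pi}, \qquad
      d_y = \tan(\theta\,\tfrac{\pi}{180})\, d_x . $$
   Equivalently $d_y = d_x c / \sqrt{1 - c^2}$ with $c = r_g/d_x$, which the
   test suite uses as an independent oracle.
4. **Curve reconstruction.** The $d_y$ are pairwise differences of $f$ at
   known $x$ positions; `fit_shape()` reconstructs $f$ by
   equality-constrained linear least squares over three local cubics joined
   smoothly at two interior knots (or, alternatively, a single fifth-degree
   polynomial).

```{r example}
rg <- tibble::tibble(
  enumerate_contrasts(tibble::tibble(bin = 1:8,
                                     x_rep = seq(-2, 2, length.out = 8))),
  rg = -0.1 * (x_control - x_case), se = 0.02
)[, c("case_bin", "control_bin", "x_case", "x_control", "rg", "se")]
fit <- fit_shape(transform_rg(rg))
glance(fit)
```

## Filtering rules

All in-bounds correlation estimates enter the fit regardless of
significance. Three kinds of record are excluded, each with a distinct
reason code carried through the distance table:

* `not_estimated` — the upstream estimator failed (missing `rg`);
* `out_of_bounds` — $|r_g| > 1$, possible for summary-statistic estimators
  that are not constrained to the correlation scale;
* `ratio_out_of_domain` — $|r_g/d_x| \ge 1$, which leaves the arc-cosine
  domain. This can happen when $d_x < 1$ on the chosen scale. The record is
  excluded rather than clamped: clamping would fabricate a 90° angle and an
  infinite $d_y$.

## Scale dependence and the sign convention

The printed transform divides $r_g$ by $d_x$ *inside* the arc-cosine, so the
inferred shape depends on the measurement scale of $x$ (changing the scale
of $x$ changes more than the x-axis labelling). The transform is implemented
literally, with no silently corrected variant; users comparing traits should
keep this in mind, and the representative-value convention (`median`,
`midpoint` or `index`) is therefore configurable but deliberately explicit.

Because the case group is the *lower* bin, a positive $r_g$ means "the
genetics of being in the lower bin correlates with the genetics of $y$", so
$d_y$ (which inherits the sign of $r_g$) estimates
$f(x_\text{case}) - f(x_\text{control})$. `fit_shape()` defaults to this
orientation (`dy_sign = "case_minus_control"`); distances already oriented
as $f(x_\text{control}) - f(x_\text{case})$ can be fitted with
`dy_sign = "control_minus_case"`. The convention was fixed by an end-to-end
simulation check: a positive linear genetic coupling must produce a rising
fitted curve, and does.

## The constrained spline and its identifiability

The spline is three local cubics $f_1, f_2, f_3$ on the segments defined by
two interior knots $i < j$ (by default at the thirds of the
representative-value range, configurable). The coefficients minimise

$$ \sum_{\text{pairs}} \left( d_y^{\text{obs}} -
   \left[ f_*(x_\text{case}) - f_*(x_\text{control}) \right] \right)^2 $$

subject to the neighbouring cubics agreeing at the knots. Agreement is
enforced for the value and the first and second derivative — six equality
constraints. Derivative matching alone would allow the fitted "function" to
jump at a knot, contradicting the requirement that the three cubics
collectively form a smooth function, so value matching is included; the
twelve raw coefficients then carry $12 - 6 = 6$ free parameters.

Only *differences* of $f$ are observed, so one of those six parameters — a
constant shift — is unidentifiable. The system is solved deterministically
by nullspace elimination and a minimum-norm SVD solve (no iterative
optimisation, no convergence tolerance, no seed), and the shift is fixed by
the anchor policy: by default the mean of $f$ over the bin representative
values is zero, matching the relative liability scale on which results are
read. Consequences, verified in the tests:

* any generating function inside the spline space (including any global
  cubic) is recovered exactly, up to the additive constant;
* linear generating data leave no spurious curvature
  ($\max |f''| \le 10^{-6}$);
* the constrained solution agrees with an unconstrained least-squares fit
  on the truncated-power spline basis and with brute-force numerical
  minimisation over the same function space.

Identification needs at least six distinct representative values for the
spline (six free parameters) and at least `degree + 1` for the polynomial;
rank deficiency beyond the known constant-shift nullspace raises an
`underdetermined` error rather than returning an arbitrary curve. If a knot
interval contains no pair endpoint, the corresponding local cubic would be
unidentified; `fit_shape()` warns and falls back to the fifth-degree
polynomial. Curves are never extrapolated outside the fitted domain. For
the polynomial estimator the monomial basis is centred at the domain
midpoint for numerical conditioning; the reported coefficients are on the
centred basis, with the centre stored alongside.

## Uncertainty

Genetic correlations arrive with standard errors. `curve_envelope()`
propagates them by resampling each $r_g$ independently from
$\mathcal{N}(r_g, \mathrm{se}^2)$ (100 times by default) and rerunning the
*entire* pipeline on each resample — including the out-of-bounds exclusion,
so resampled values that leave $[-1, 1]$ are excluded exactly like
first-pass ones, not truncated. All resampled curves are retained
(spaghetti-style presentation is possible) and pointwise 2.5%/97.5% bands
with a median are computed on top. Per-cycle refit failures are counted and
skipped, never retried, because retrying would condition the envelope on
success.

A known limitation, inherited from the resampling design: the $r_g$
estimates of bin pairs that share a bin are *correlated* (they reuse the
same case or control GWAS and the same $y$ statistics), while the envelope
resamples them independently. Independent perturbations partially average
out across the roughly $K-1$ pairs that touch each bin, so the envelope
understates the correlated component of uncertainty by a factor of up to
$\sqrt{K-1}$. In the package's null simulations the fitted curve's total
wiggle is therefore typically 3–5 envelope half-widths even though the
curve is flat in every meaningful sense (no systematic shape, amplitude at
the per-pair noise level and an order of magnitude below real signals).
Bands should be read as *lower bounds* on uncertainty; formally accounting
for the cross-pair correlation would require the joint covariance of the
$r_g$ estimates, which summary-level inputs do not provide.

## The simulator: what it emulates, and what a green test establishes

`simulate_cohort()` generates cohorts of `n` individuals typed at `m`
independent biallelic variants (allele frequencies uniform on
$(0.05, 0.95)$), builds standardised additive scores, and composes the two
traits so that $\mathrm{var}(a_x)/\mathrm{var}(x) = h^2_x$ and
$\mathrm{var}(a_y) = 1$. Defaults — $n = 20{,}000$, $m = 2{,}000$, $h^2_x =
0.5$, ten equal bins, $\mathrm{sd}(e_y) = 1$ — are desk-scale: large enough
for the qualitative shape signals to clear the noise, small enough that a
full end-to-end run takes seconds. GWAS effect estimation replaces the
LD-score machinery with the direct correlation of per-variant effect
vectors plus a delete-one-block jackknife standard error (20 contiguous
blocks), which is valid because the simulated variants are in linkage
equilibrium. The $y$-side effect vector uses the noise-free genetic
component by default so that correlation noise is driven by the contrast
GWAS, the quantity of interest.

Two consequences of this stand-in deserve emphasis:

* **Attenuation.** The raw correlation of noisy effect vectors is shrunk
  towards zero by estimation noise (regression dilution), unlike LD-score
  regression, whose intercept absorbs the noise term. Recovered curve
  *amplitudes* in simulation are therefore conservative; shapes are
  preserved because attenuation varies smoothly across pairs.
* **Out-of-bound estimates are rare** at the default scale, so the
  exclusion machinery is exercised mainly by the resampling envelope and by
  dedicated unit tests.

### Couplings and the detectability boundary

The central assumption of the method is that binning $x$ is informative
about $a_x$ *differentially across the range of $x$*. If every variant's
effect on $x$ is homogeneous across the whole range, all bin-pair contrast
GWASs are genetically the same study up to scale — their population effect
vectors are perfectly correlated (`true_contrast_effects()` verifies this
at $r \ge 0.999$) — and their genetic correlation with $y$ is one number
regardless of the pair. No nonlinear shape can then be detected, however
nonlinear the true coupling. The simulator makes this boundary explicit:

* `linear` and `null` use a homogeneous additive $a_x$: the correct
  regimes for a monotone signal and for a flat negative control.
* `quadratic` keeps the coupling
  $a_y = \lambda\,(a_x^2 - \mathrm{E}[a_x^2]) + u$ but equips $a_x$ with
  *tail-activated* components — distinct variant sets expressed in the
  lower and upper halves of the baseline score — the genetic-effect
  heterogeneity without which the quadratic signal is provably invisible.
  Setting `heterogeneous_x = FALSE` reproduces the homogeneous
  (blind) regime, where the recovered curve is flat despite the strong
  nonlinear coupling: a feature of the method's assumptions, not a bug of
  the simulator.
* `two_tail` models the mechanism "y can push x up or down, depending on
  the individual": the $y$ liability displaces $x$ away from its baseline
  by $\kappa\,w_i \max(a_y, 0)$ with a per-individual direction
  $w_i = \pm 1$. Carriers of $y$ risk alleles are thereby enriched in
  *both* tails of $x$, producing the U-shaped relationship seen between
  sleep duration and depression. A symmetric signed construction (e.g.
  $x = a_0 - \kappa a_s + \kappa a_l$ with $a_y = a_s + a_l$) does *not*
  produce a U: enrichment for one tail component is exactly offset by
  depletion of the other, so $\mathrm{E}[a_y \mid x] \equiv 0$; the
  one-sided displacement breaks that symmetry.

A green shape-recovery test therefore establishes that the pipeline turns
heterogeneous tail-specific genetic signal into the correct qualitative
curve at biobank-plausible effect sizes — not that the method can detect
nonlinearity under homogeneous architectures (it cannot, by design), and
not that simulated amplitudes match empirical liability units (they are
attenuated, and the transform is scale dependent). Real-data features the
simulator deliberately omits: linkage disequilibrium, relatedness,
covariates, ascertainment, and LD-score regression itself.

Under the homogeneous `linear` coupling the population $r_g$ is the *same*
for every bin pair, so even noiseless inputs would not reproduce
$d_y \propto d_x$ exactly; the near-linear recovered curve at the default
scale arises because estimation noise attenuates weak (small-$d_x$) pairs
more strongly. The linear recovery test accordingly asserts monotonicity
and amplitude, not a curvature bound.

## Numerical and design choices

* **Quantile assignment** uses rank-based cutpoints (the value at rank
  $\lceil qn \rceil$), ties at a cutpoint falling to the lower bin:
  deterministic, order-independent, platform-exact. Value bins are
  left-closed categories with open-ended extremes (so "4 hours" means
  $[4, 5)$ and ">10" means $\ge 11$ for integer recordings).
* **Small bins** (default threshold 100 members) warn rather than error —
  tail bins are deliberately small in tail-emphasis designs. Empty bins are
  errors naming the bin.
* **Weighting** of pairs by $1/\mathrm{se}^2$ is available
  (`weight_by_se = TRUE`) but off by default; the reference objective is
  unweighted.
* **Determinism**: every stochastic step (cohort generation, resampling)
  flows from an explicit integer seed through an isolated RNG scope, so
  identical seeds give bit-identical rg tables, curves and envelopes, and
  library calls never disturb the caller's RNG state.
* **Output** is TSV at 12 significant digits plus JSON sidecars (curve
  coefficients, run metadata with config echo, seed and versions). The
  `exec/rgshape` script exposes `bins`, `fit`, `simulate` and `envelope`
  subcommands over `run_pipeline()`.

## Known limitations

* The transform is scale dependent (see above); comparisons across traits
  or units require care, and y-axis values are relative — comparable within
  a curve, not between outcomes.
* Envelope bands understate uncertainty shared across overlapping pairs
  (see *Uncertainty*).
* The method is blind to nonlinear couplings over fully homogeneous
  additive architectures; a flat curve is evidence of *either* no
  relationship *or* no usable heterogeneity.
* No automatic bin-scheme selection is attempted: the number and placement
  of bins trade per-GWAS power against resolution and must be chosen per
  trait; tail-emphasis designs such as `bmi_bin_widths()` reflect the
  hypothesis that trait-specific signal concentrates in the tails.
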