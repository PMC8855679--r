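---
title: "Optimizing a colorimetric glycogen assay by response surface methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing a colorimetric glycogen assay by response surface methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assayrsm)
```

## The assay and the modelling problem

In the phenol–sulfuric acid method, concentrated sulfuric acid dehydrates
carbohydrate to furfural derivatives that condense with phenol into an
orange chromophore read near 490 nm. The signal depends jointly on the
volumes of phenol, acid and water in the reaction, and the dependencies
interact: the acid supplies both reactant and the heat of dilution that
drives the reaction, and the aqueous volume dilutes the chromophore. A
one-variable-at-a-time search cannot see those interactions, so the
package works with a designed multifactor experiment instead.

Throughout, reagent volumes are **coded**: a `factor_spec()` maps a volume
to `(volume - center)/half_range`, so the factorial levels sit at ±1 and
the center at 0. Coding makes the design symmetric in all directions and
puts all coefficients on a comparable scale. The uncoded grid is a
property of each lab's pipetting scheme and is deliberately a user input,
never a package constant.

## The design

`ccd_design()` builds a rotatable central composite design: the $2^k$
factorial cube, $2k$ axial points at distance $\alpha = (2^k)^{1/4}$
(1.682 for $k = 3$, the value that makes prediction variance a function
of distance from the center only), and $n \ge 2$ center replicates. Two
properties are enforced rather than left to chance:

* the run order is randomized by a recorded integer seed, so a run sheet
  can be regenerated exactly, and
* one center replicate is pinned to the first and one to the last
  position, with the rest dispersed by the randomization. The center
  points then double as a process-stability control spanning the whole
  session.

Axial points may decode to negative volumes. That is physically
meaningful only as "pin this reagent at 0 µl", so decoding negative
volumes errors unless the factor explicitly allows it, in which case it
warns.

## Fitting and reducing the surface

`fit_rsm()` fits the absorbance $R(x_1, x_2, x_3)$ by ordinary least
squares to a polynomial term set; the default is the full quadratic with
**all** interactions (11 terms for three factors, including the
three-way product). Standard errors come from the residual variance with
$n - p$ degrees of freedom and each coefficient carries a two-sided t
test of the hypothesis that its population value is zero.

`reduce_terms()` removes the terms whose estimates are statistically
indistinguishable from zero at level $\alpha$ (default 0.05) — that is,
terms with $p \ge \alpha$ are removed, terms with $p < \alpha$ are
established and stay. Two guards preserve model structure:

* the intercept is never removed;
* a linear term is retained whenever any retained higher-order term
  (interaction or square) involves that factor. On the packaged data this
  is exactly what keeps the linear phenol term ($p = 0.47$): the
  phenol:acid and three-way interactions are established and need it.

Higher-order terms are kept only on their own evidence; a two-way
interaction is not retained merely because the three-way term survives.
On the packaged experiment the procedure removes precisely the phenol
quadratic and the phenol:water interaction, giving the nine-term model
whose coefficients and intervals the package reproduces to the published
precision.

### AICc

`compare_aicc()` checks a reduction with the corrected AIC in its
least-squares form,

$$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2K + \frac{2K(K+1)}{n-K-1},
\qquad K = p + 1,$$

counting the error variance as an estimated parameter. This is the
convention used by the common curve-fitting packages, and it is the
convention under which the packaged comparison gives
$\Delta\mathrm{AICc} = -20.93$ in favour of the reduced model, with
evidence-ratio probability $1/(1+e^{\Delta/2}) > 99.99\%$. The
probability pair for the two orderings always sums to 1.

### Center-point drift

`center_point_drift()` computes the residuals of the center replicates
around their mean against run order and summarizes them by the mean
absolute deviation relative to the mean, passing below 5%. On the
packaged runs: mean 0.292, MAD 0.008, ratio 2.8% — a stable session. At
the generator's default noise (below), roughly one simulated session in
six fails this check; that is the check working, not a defect.

## Choosing conditions: the error-propagation objective

A condition is *precise* when small pipetting errors move the signal
little relative to its size. `worst_case_relative_error()` implements the
first-order (total differential) propagation with all error terms adding:

$$\left|\frac{\Delta R}{R}\right| \;\approx\; \frac{1}{|R|}
\sum_i \left|\frac{\partial R}{\partial x_i}\,\Delta x_i\right|$$

with analytic partials of the fitted polynomial. The default coded
perturbation is $\Delta x_i = 0.05$ per factor — a 1% error on a typical
50 µl dispense under a 10 µl-per-coded-unit map — and is overridable per
factor. The objective is exact to first order; on quadratic surfaces with
$\|\Delta\| \le 0.05$ it agrees with exhaustive sign enumeration of
$|R(x \pm \Delta) - R(x)|/|R(x)|$ to well within one percentage point
(a property the test suite checks against that oracle). It is invariant
to rescaling $R$ and monotone in each $\Delta_i$.

`find_max_response()` maximizes the fitted surface over a coded box
(multi-start L-BFGS-B with the analytic gradient); on the packaged
surface the maximizer sits on the boundary, near the volume extremes.
`find_precise_condition()` minimizes the worst-case objective subject to
pinned factors (e.g. water at its low axial level, so the protocol skips
a pipetting step), a coded box, and optionally a minimum total reaction
volume, which is linear in the coded levels once the coding maps are
supplied. The search is a seeded 32-start Nelder–Mead inside an
adaptive-barrier method for the volume constraint; in one free dimension
it switches to a dense line search. Ties between starts are broken toward
the smaller gradient-magnitude sum $\sum_i |\partial R/\partial x_i|$ —
that sum is also the natural reading of "choose the condition where the
derivatives are jointly smallest", and minimizing the relative-error
objective (which weights the same derivatives by $1/|R|$) is the
interpretation this package commits to. With the water level pinned at
−1.682 the minimizer lands at a moderate phenol level and near-center
acid, a mild extrapolation the workflow accepts because any selected
condition is re-validated with calibration curves.

Degenerate inputs are defined rather than undefined: all-zero deltas make
the objective identically zero (the search warns and returns the
smallest-gradient feasible point); a vanishing predicted response makes
relative error meaningless and errors at the requested point (and is
treated as infinitely imprecise inside the search).

## Standard curves and precision

`fit_standard_curve()` fits absorbance against analyte mass by OLS over
the linear region only: observations above the saturation cap (default
1.6 A.U., inclusive at the boundary and configurable) are excluded so
Beer's-law deviation does not bend the line. `detect_outliers_rout()`
reimplements the robust-fit-then-FDR outlier identification scheme from
its published description — an M-estimated line (IRLS), a robust residual
scale from the median absolute residual, then a Benjamini–Hochberg test
of the absolute studentized residuals at rate $Q$ (default 1%). Because
the original procedure lives in proprietary software, this is an
independent implementation of the idea, validated on constructed
fixtures (a point displaced ten robust scales is flagged alone; flags are
invariant under affine rescaling). Flags are **advisory**: the fit never
removes a point on its own, because the decision to discard data needs an
experimental reason as well as a statistical one — the packaged
experiment itself flagged two candidate points and removed only the one
with a documented pipetting deviation.

%CV is only meaningful when zero signal means zero analyte, so
`intra_assay_cv()` expects blank-corrected input (`blank_correct()`
subtracts the curve intercept; refitting blanked data gives intercept 0).
It reports per-level $100\,\mathrm{sd}/\mathrm{mean}$ and a weighted
average across levels, weighting by replicate count — the simplest
defensible weighting given that "weighted" is otherwise unspecified;
levels reduced to one usable replicate are excluded by `cv_eligible()`
and non-positive level means are flagged undefined rather than reported
as a sign-flipped percentage.

## Quantification and stoichiometry

`tissue_glycogen()` converts a curve readout into content:

$$\frac{m_\mathrm{glycogen}}{m_\mathrm{tissue}} =
\frac{m_\mathrm{curve}/V_\mathrm{assayed}\cdot V_\mathrm{sample}}
{m_\mathrm{tissue}}\quad(\mu g/mg).$$

This is the only dimensionally consistent reading of the assay's
dilution bookkeeping (the aliquot concentration scaled to the full
dissolution volume, normalized by tissue mass), and the implementation
documents it as such: the function is homogeneous of degree +1 in
$m_\mathrm{curve}$ and $V_\mathrm{sample}$ and −1 in the other two
arguments, which the tests assert directly.

A glycogen particle of $N$ glucosyl units has molar mass $162N + 18$
g/mol (each polymerized unit loses one water; the chain keeps one). So a
$10^6$ g/mol particle holds $\lfloor(10^6-18)/162\rfloor = 6172$ glucose
units, and $N = 1$ recovers free glucose at 180 g/mol. These conversions
drive `glucose_equivalents()` (mass/180 or mass/162) and the molar scale
of `fractional_yield()`, which recomputes $N$ from the configured
particle mass rather than hard-coding 6172. Glucose standards
systematically out-slope glycogen standards: hydrolysis in the assay is
incomplete, and each released unit regains its water of condensation
(180/162). Quantifying glycogen against a glucose curve therefore reads
low on the mass scale, which is why the package (like the protocol it
implements) prefers matching the standard to the analyte, and reports
glucose-curve readings of glycogen as molar glucose equivalents.

`mean_difference_ci()` supports the verification comparisons (model
prediction vs replicate measurements; co-precipitant interference):
difference of means with a pooled-variance t interval (Welch optional).
When one side is a set of model predictions the interval deliberately
ignores the prediction's own uncertainty — it answers "do the replicates
sit where the model says", not "are the two estimates compatible".

## The synthetic generators

Every stage has a seeded generator emulating the statistical structure
the real data show, so the whole pipeline runs and is testable offline:

* `simulate_surface_measurements()` — the fitted surface plus additive
  iid Gaussian noise, SD defaulting to **0.013 A.U.**, the standard
  deviation of the packaged experiment's six center replicates. Additive
  noise matches how design runs are summarized (replicate SD).
* `simulate_standard_curve()` — a Beer's-law line with **multiplicative**
  noise (SD = CV, default **0.07**, the middle of the assay's observed
  5–10% intra-assay band), matching how curves are summarized (%CV);
  readings above 1.6 A.U. are flagged saturating. With the default slope
  0.07279 A.U./µg and blank 0.02, saturation cuts in just above 21.7 µg.
* `simulate_extraction()` — per-spin geometric bookkeeping: glycogen
  retained with a per-spin recovery fraction (default 0.93), free glucose
  carried over at a fraction of 0.005 per spin. The carryover is a
  synthetic choice: the experiments only show that one spin removes
  essentially all free sugar, so the default leaves 0.5% after one spin.
* `simulate_yield_readings()` — paired readings of the same glycogen
  aliquots against glycogen and glucose curves, with hydrolysis
  completeness defaulting to **0.837** so the mass-scale fractional yield
  $c \cdot 180/162$ centers at 0.93, inside the observed 91–95% band.
* `simulate_tissue_panel()` — tissue samples of known content through
  extraction, curve calibration and quantification. Retention defaults to
  **1.0** for the one-spin tissue protocol: the verification experiments
  show a single precipitation does not remove glycogen, and the yield
  band above reflects in-reaction hydrolysis, not extraction loss.
  Partial recovery remains a parameter for modelling lossy protocols. At
  the defaults, a six-sample panel in duplicate recovers the configured
  content within 10% in well over 90% of seeds.

What passing simulations do **not** show: the generators are
homoscedastic within each stage, have no plate-position or session
effects, no drift (every simulated session is in control on average), no
heteroscedastic curve tails beyond the multiplicative structure, and no
matrix effects from real tissue. They validate the arithmetic and the
statistical machinery under the stated noise model, not the chemistry.

## Numerical choices and limitations

* OLS is solved by QR; rank deficiency is an explicit `singular-design`
  error, not a silent drop. The normal-equations oracle in the test suite
  agrees to machine precision.
* Confidence intervals are t-based with residual degrees of freedom —
  asymptotic in the usual curve-fitting sense; no profile or sandwich
  variants.
* Prediction flags extrapolation beyond the axial distance with a 10⁻³
  slack so printed 3-decimal axial levels (±1.682) do not count as
  outside.
* The optimizer is deterministic given its seed; quadratic surfaces have
  few basins, so 32 starts plus the box corners are ample.
* Test problem sizes: 200-replicate Monte-Carlo for term removal and the
  %CV band, 500 for coefficient CI coverage (observed rates fall in
  90–98%), 1000 for the null-difference coverage check, 60–100 seeds for
  end-to-end recovery — sizes chosen so the whole suite runs in a few
  minutes on one CPU while keeping the Monte-Carlo error well below the
  bands being checked.
* Out of scope by design: Box–Behnken or fractional designs, blocking,
  lack-of-fit F tests, 4PL curve shapes, inter-assay CV, and any
  modelling of the enzymatic (amyloglucosidase) or anthrone chemistry.
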