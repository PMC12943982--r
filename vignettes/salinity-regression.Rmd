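---
title: "Modelling rice shoot biomass under salinity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rice shoot biomass under salinity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltreg)
```

## The problem

Screening rice for salinity tolerance at scale requires proxies that are
fast to measure. Four candidate traits are routinely collected on
salt-grown plants: the SPAD chlorophyll index (X1), stomatal conductance
Gs in mmol m^-2^ s^-1^ (X2), shoot sap Na^+^ in mM (X3) and shoot sap K^+^
in mM (X4). The question the package addresses is which of these traits
predict shoot dry weight (SDW, g/plant) at the vegetative stage, and with
what functional shape — in particular whether shoot Na^+^, the classical
breeding target, carries predictive weight once the other traits are
accounted for.

The modelling vehicle is a full quadratic response surface in the four
raw-unit traits,

$$Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{i,i} X_i^2 +
      \sum_{i<j} \beta_{i,j} X_i X_j + \varepsilon,$$

15 candidate terms in all, pruned to the largest set whose slopes are all
statistically significant under robust inference. The reference fit
shipped with the package (`rice_sdw_model()`) retains five terms — Gs and
K^+^ linearly, with negative curvature in both, plus a negative SPAD
quadratic — and no Na^+^ term, no intercept and no cross terms.

## Estimation machinery

**SVD fitting.** Every least-squares fit runs through a singular value
decomposition with singular values below `rel_tol` (default 1e-10)
times the largest one treated as zero. A raw-unit quadratic design is
severely ill-conditioned (columns such as K^+^ and (K^+^)^2^ correlate
above 0.99), and the truncated pseudo-inverse yields the minimum-norm
solution on exactly rank-deficient designs instead of failing. No
centering or scaling is applied anywhere, so coefficients stay in
g/plant per raw trait unit and are directly comparable to the published
values.

**Leverage and holdout residuals.** Leverages come from the retained
singular directions, and the predicted (PRESS) residual
$\tilde e_i = e_i/(1-h_{ii})$ equals the error on record $i$ of a model
refitted without that record — an identity the test suite verifies
against literal leave-one-out refits. All performance measures (RMSE_HO,
MAE_HO, R^2^_HO) are computed from these holdout residuals; the in-sample
adjusted R^2^ completes the set.

**TSS convention.** For models without an intercept the total sum of
squares is uncentered (`sum(y^2)`) by default, with a switch to the
centered convention; both are reported by the pipeline because the
choice is genuinely ambiguous for intercept-free models and materially
changes R^2^-type measures. The adjusted-R^2^ centering constant is 1
with an intercept, 0 without.

**HC3 inference.** Slope covariances use the HC3 sandwich estimator,
whose inner weights are the squared predicted residuals
$e_i^2/(1-h_{ii})^2$ — each record's influence is judged by its own
holdout error, making the standard errors robust to heteroskedasticity
and to moderate leverage. Per-slope p-values refer
$\hat\beta_j/\sqrt{S_{jj}}$ to a Student t on $n-p$ degrees of freedom.

## Term selection

`run_msra()` searches for a maximal-cardinality all-significant term set
in three phases: backward elimination (repeatedly drop the largest
robust p-value at or above `alpha`), re-entry (add back a removed term
if the refitted model is all-significant), and exchange (swap a retained
term for a removed one if the swapped model is all-significant and has
strictly more terms or a strictly larger minimum |t|). P-values are
recomputed after every accepted change; ties remove the term latest in
canonical order, making the search deterministic. `alpha` defaults to
0.05, the field's default, consistent with the reference model in which
every |slope|/SD exceeds 4.

The three-phase structure is this package's own reconstruction of a
stepwise scheme described elsewhere only by its step counts, and it is
worth being clear about its behavior on strongly collinear candidates:
near-equivalent reparametrizations (an intercept-plus-linear combination
standing in for a pure square, or a cross term standing in for two
squares of correlated traits) can be all-significant too, and on
simulated data the search frequently terminates in such a
representation, or in a larger all-significant superset sustained by
mutual suppression. Recovering the exact generating term set is
therefore *not* a property this selector has at realistic effect sizes
— the test suite asserts instead what does hold: the final set is
all-significant, the trace replays deterministically, and the selected
model's holdout error is comparable to the generating structure's. Users
should read the selected set as *one* parsimonious all-significant
representation, with the strongly identified conductance and K^+^
structure stable across runs.

## Outlier screening

`run_codpa()` repeats fit → externally studentized residual p-values →
Benjamini–Hochberg step-up at `max_fdr` (default 30%) → purge all
flagged records, one cycle per purge, until a cycle flags nothing. The
externally studentized residual uses the closed-form deletion identity,
so each record is judged against a scale estimate that excludes it, and
is exactly Student t on $n-p-1$ degrees of freedom under the null. The
BH family is the current record count each cycle; removing all flagged
records per cycle (rather than one at a time) is what gives per-cycle
flag counts their meaning. The screen runs on a fixed model structure —
in the pipeline, the structure chosen by the selection step — and stops
with a warning rather than purging below $n = p + 2$.

## Assumption diagnostics

**Heteroskedasticity** (`run_mhtra()`): the squared predicted residuals
are regressed on the full 15-term quadratic in the four raw traits
(a White-style auxiliary regression, reusing the same SVD fitting path),
and the auxiliary overall-F p-value and adjusted R^2^ are reported. The
fit is called homoskedastic exactly when the p-value is at least
`alpha_het` (default 0.05) *and* the auxiliary adjusted R^2^ is below
`r2_ceiling` (default 0.05 — any small ceiling serves, since a
homoskedastic fit leaves essentially nothing for the auxiliary surface
to explain). The weighted-least-squares "relaxing" step sometimes paired
with such tests is out of scope: the verdict is reported, not acted on.

**Normality** (`mc_jarque_bera()`): the Jarque–Bera statistic
$JB = \tfrac{n}{6}(g_1^2 + \tfrac{1}{4}(g_2-3)^2)$ is calibrated against
`n_mc` (default 10,000) simulated standard-normal samples of the same
size rather than its asymptotic chi-square, which is inaccurate at
$n \approx 100$. The p-value uses the add-one estimator
$(1 + \#\{JB^* \ge JB\})/(1 + n_{mc})$, never exactly zero and
bit-reproducible given the seed.

## Prediction engine

A `final_model` carries slopes, the HC3 covariance $S$, the residual SD
and the interval degrees of freedom. The mean response is the direct
polynomial evaluation; its variance is the quadratic form $x^T S x$ in
the observation vector, clipped at zero against rounding; intervals are
mean $\pm t_{(1+\gamma)/2,\nu}\sqrt{x^T S x}$ with $\gamma = 0.5$ by
default. These are confidence bands for the *mean* response — the
residual variance is deliberately not added, matching how the reference
surfaces are defined; a prediction-interval option adds it for users who
want single-observation bands. Five scenario templates
(`figure_scenario(1:5)`) sweep one trait over its physiological range
(SPAD 10–50 step 1, Gs 10–90 step 2, K^+^ 10–300 mM step 5) at fixed
levels of the other two. Because the reference model has no cross terms,
the surface is additive in the three traits, and the interior optima are
closed-form: Gs at $0.04874/(2 \times 5.280\times10^{-4}) \approx 46.2$
mmol m^-2^ s^-1^ and K^+^ at
$0.01261/(2\times3.009\times10^{-5}) \approx 209.5$ mM.

## The synthetic generator

`generate_phenotypes()` emulates the structure of the glasshouse table
the pipeline targets: 10 genotypes × 3 salinity levels (0/50/100 mM
NaCl) with replicates trimmed to 146 records. Genotype baselines are
drawn once per genotype from the middle half of each trait's range;
salinity shifts traits monotonically (defaults: SPAD −5/−10 units,
Gs −20/−40 mmol m^-2^ s^-1^, K^+^ −60/−120 mM, Na^+^ +100/+200 mM at
50/100 mM NaCl), replicate jitter is normal with SD 5% of each range,
and values are clipped to the physiological ranges (SPAD 10–50,
Gs 10–90, K^+^ 10–300, Na^+^ 0–400 mM). The effect sizes are chosen so
generated traits span the same ranges the prediction grids cover,
consistent with reported salinity responses in rice (conductance
collapsing by about two-thirds, sap K^+^ falling several-fold). The
response is the quadratic model mean under configurable true slopes
(default: the reference model's five slopes, so Na^+^ truly carries no
effect) plus Gaussian noise with SD 0.28 g/plant. By default 15% of
records are displaced by 4 noise-SDs, emulating the contamination level
a staged FDR screen finds in real tables of this kind; a planted outlier
whose downward shift would cross zero is displaced upward instead, since
the non-negativity floor of dry weights would otherwise mask it.

What the generator does *not* emulate: genotype-by-treatment
interactions beyond additive shifts, within-plant correlation of
replicate measurements, measurement error in the predictors, and any
mechanistic physiology. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the machinery under the
stated statistical model, not the biological fidelity of any particular
fit. Na^+^ values, never tabulated in the reference work, are generated
over a plausible 0–400 mM sap range and are, by construction, inert in
the response.

## Numerical choices and degenerate inputs

- Singular-value truncation at `rel_tol = 1e-10` relative; configurable.
- Residual SD uses denominator $n - p$ with $p$ the term count, also on
  rank-deficient designs.
- A slope with zero robust SD gets p = 1 if the slope is zero, else 0;
  a record with leverage numerically 1 makes the holdout residual
  undefined (error in `predicted_residuals()`) and is flagged
  unconditionally by the outlier screen.
- Constant responses are rejected where an R^2^ would be undefined;
  exactly constant squared predicted residuals short-circuit the
  heteroskedasticity test to a homoskedastic verdict.
- All dense linear algebra is double precision; no iterative solvers.

## Problem sizes used in validation

The test suite exercises leave-one-out identities exhaustively at
$n \le 30$, calibration of the diagnostic tests with 100–150 replicates
of the 146-record study design, the selection and screening algorithms
on full-size (146–150 record) synthetic tables, and the parameter
recovery experiment with 8–25 replicates. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerance bands while
keeping the default test run fast.

## Known limitations

- The stepwise selector inherits the classical instabilities of
  significance-driven subset search under collinearity (see above); its
  audit trail is the intended mitigation, not a cure.
- The outlier screen's FDR guarantee is per cycle, not family-wise
  across cycles.
- Whether "unbiased" small-sample refinements beyond HC3's leverage
  correction should be applied, and whether published R^2^-type measures
  for intercept-free models used centered or uncentered totals, are left
  as explicit configuration rather than guessed; the pipeline reports
  both conventions.
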