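---
title: "Methods: antecedent-flow memory analysis with hydromem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antecedent-flow memory analysis with hydromem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydromem)
```

## The scientific problem

In remote headwater streams — the motivating setting is a high-Andean
paramo micro-catchment of a few tenths of a km² — streamflow is rarely
gauged, yet flow history is a first-order control on benthic
macroinvertebrate communities. hydromem implements a pragmatic chain for
such data-scarce systems:

1. reconstruct daily discharge from daily rainfall with a conceptual
   rainfall-runoff model;
2. summarise the flow history over the 3, 6 and 9 days preceding each
   biological sampling event ("antecedent windows") through six
   descriptors;
3. compute taxonomic and fuzzy-trait functional diversity per event; and
4. ask which antecedent window, and which descriptor within it, best
   explains diversity — the "hydrological memory" of the community,
   meant strictly as a statistical construct over time-integrated flow
   descriptors, not an organismal mechanism.

Because a study of this kind cannot be validated against gauges, the
package ships a synthetic-data generator with a *planted* flow-diversity
dependence at a known window, so the whole chain can be verified by
simulation: if the analysis cannot recover a signal it was given, it
cannot be trusted on field data.

## Hydrological simulator

**Runoff depth.** Daily direct-runoff depth follows the curve-number
method: potential retention $S = 25400/\mathrm{CN} - 254$ (mm), initial
abstraction $I_a = \lambda S$, and
$Q = (P - I_a)^2 / (P - I_a + S)$ for $P > I_a$, else 0. The default
$\mathrm{CN} = 86.54$ describes wet antecedent conditions (the wet-season
ARC III adjustment is assumed already folded into the supplied CN; no
further antecedent-moisture conversion is applied). $\lambda$ defaults to
the conventional 0.2 and is exposed in `catchment_config()`. The method
is applied day by day with no inter-day soil-moisture accounting, which
matches a single-CN daily setup.

**Routing.** Excess depth is routed with the Clark unit hydrograph: the
standard dimensionless S-shaped time-area curve
($1.414\,(t/t_c)^{1.5}$ rising, mirrored falling) is differenced into an
inflow histogram and passed through a linear reservoir with coefficient
$c = \Delta t / (R + \Delta t/2)$. A numerical subtlety motivates the
internal sub-daily step (default 1 h): at $\Delta t = 24$ h with
$R = 12$ h the coefficient is exactly 1 and routing degenerates to the
identity, so daily-step routing would do nothing. Sub-stepping then
aggregating to daily ordinates is the standard resolution. The ordinate
tail is truncated once cumulative outflow reaches $1 - 10^{-6}$ and
renormalised; with $R = 0$ the coefficient is capped at 1, giving pure
translation. Depth converts to discharge as
$\mathrm{mm} \times \mathrm{km}^2 \times 1000 / 86400$ m³ s⁻¹.

**Baseflow.** Exponential recession from $Q_0 = 0.005$ m³ s⁻¹ with
constant $k = 0.95\,\mathrm{day}^{-1}$. Pure recession from the series
start decays to effectively zero over multi-year runs, which contradicts
the sustained minimal flows such streams exhibit; the default
`event_reset` mode therefore restarts the recession at $Q_0$ at each
wet-spell onset (first day with positive excess after a dry day). Both
modes are implemented and flagged; `pure_recession` gives the closed form
$Q_0 k^t$ used in tests.

## Antecedent descriptors

For each sampling event and window length $w$ the $w$ daily flows
*preceding* the sampling day (which is excluded) yield, with
$\Delta_i = q_i - q_{i-1}$ computed only between consecutive days inside
the window ($w - 1$ differences):

* `q_mean` — mean discharge;
* `rb` — Richards–Baker flashiness, $\sum_i |\Delta_i| / \sum_i q_i$
  (all $w$ flows in the denominator; defined as 0 on an all-zero window);
* `n_rise` — number of rises ($\Delta_i > 0$; ties count neither way);
* `sum_rise`, `sum_fall` — cumulative magnitudes of rises and falls,
  both reported non-negative;
* `sum_abs` — $\sum |\Delta_i|$, identically `sum_rise + sum_fall`.

For non-negative flows `rb` is bounded by 2 since
$|\Delta_i| \le q_i + q_{i-1}$.

## Diversity indices

Taxonomic indices use natural logarithms: Shannon $H = -\sum p_i \ln
p_i$, Pielou $E = H/\ln S$ (undefined for a monoculture and returned as
NA), and Simpson *dominance* $D = \sum p_i^2$ (the concentration
orientation, so $D = 1$ for a monoculture).

Functional indices work from a families × 41-category fuzzy trait matrix
over eight traits (feeding habits, respiration, body form, maximum body
size, body flexibility, locomotion, reproduction, exoskeleton hardness),
with affinity scores in $[0, 3]$. Scores are normalised within each trait
block to probability profiles; all-zero blocks are flagged missing rather
than fatal. The pairwise family distance is a Gower-type construction
made explicit here because the legacy tooling this emulates does not
document its metric: per trait, half the $L_1$ distance between profiles
(total variation, in $[0,1]$), averaged over traits scored for both
families. On it are built:

* Rao's quadratic entropy $\sum_{ij} d_{ij} p_i p_j$;
* FAD1, the raw *sum* of pairwise distances among present families
  (following the original functional-attribute-diversity definition;
  abundance-blind beyond presence);
* wFDc, the abundance-weighted mean Euclidean distance of families from
  the abundance-weighted centroid in concatenated profile space — the
  most common reading of "community-weighted functional divergence".
  Both of the latter forms are deliberately isolated behind their own
  functions so an alternative convention can be substituted without
  touching anything else.

## The statistical stage

For every window each index is modelled as
$y = \alpha + \sum_j s_j(x_j)$ over the six descriptors, each $s_j$ a
penalised thin-plate smooth with basis dimension $k = 3$ (at most 2
effective df), so penalisation can shrink terms to effectively linear.
Events are few, so parsimony is deliberate. Model families: Gaussian for
$H$, Rao, FAD1, wFDc; a logit-link beta family for the
proportion-bounded $E$ and $D$, after the usual boundary squeeze
$y' = (y(n-1) + 0.5)/n$.

For Gaussian fits an AR(1) residual correlation over the event index is
attempted first (additive mixed model); failure to converge — frequent
at these sample sizes with six smooths — engages the documented fallback,
a standard GAM with an added $k = 3$ smooth of the event index. Beta
fits go straight to the fallback form because the mixed-model route does
not support that family. Two numerical choices matter and were made
deliberately:

* **Smoothness selection is REML by default** (`"GCV.Cp"` is available
  as an option). At 20–60 events GCV's selection noise is large enough
  to destabilise the drop-one importance ranking below; REML is the
  standard small-sample choice and the beta family requires (RE)ML in
  any case.
* **Double-penalty shrinkage** (`select = TRUE`) lets an uninformative
  smooth be penalised away entirely. Without it, refitting during
  drop-one importance credits noise descriptors with spurious
  $\Delta R^2_{adj}$; with it their deltas collapse toward zero.

**Metrics and triage.** $R^2 = 1 - SSE/SST$ on the response scale;
$R^2_{adj} = 1 - (1 - R^2)(n-1)/(n - p_{\mathrm{eff}} - 1)$ with
$p_{\mathrm{eff}}$ the summed effective df of all model terms excluding
the intercept (the adjustment is not uniquely defined for penalised
models; this choice is isolated in `model_metrics()`);
$RMSE = \sqrt{SSE/n}$. Residual normality is screened by Shapiro–Wilk
($p \ge 0.05$ read as approximately normal) — a strict check only for
Gaussian fits, a descriptive diagnostic for beta fits. A constant
response is assigned $R^2 = 0$ by convention and fitted as intercept
only.

**Window selection** takes the window with the highest mean
$R^2_{adj}$ across responses, ties broken by lower mean RMSE, then by
the shortest window. Responses failing the normality screen at the
selected window are excluded from the importance stage (they remain in
the comparison table).

**Drop-one importance** refits each retained model without each
descriptor in turn, with the same family and smooth specification, and
reports $\Delta R^2_{adj} = R^2_{adj}(\text{full}) -
R^2_{adj}(\text{reduced})$; negative values are legitimate (removing a
term can raise the adjusted value) and preserved. No multiple-testing
correction is applied anywhere: the Spearman screen is exploratory and
reported without p-values.

## What the synthetic generator emulates — and what it does not

`gen_rainfall()` uses a two-state (wet/dry) Markov occurrence chain with
gamma wet-day amounts, the simplest generator reproducing rainfall
intermittency with spell persistence. Defaults
(`p_wet_after_dry = 0.5`, `p_wet_after_wet = 0.7`, shape 1) describe a
wet tropical-alpine regime of frequent light rain; the gamma scale is
solved so the *unconditional* mean is the target 3.1 mm day⁻¹, and the
implied daily maxima over a multi-year record are of order 40–60 mm.
These are calibration-free choices documented as such.

`gen_communities()` plants the flow-diversity link on community
*evenness*: the chosen driver descriptor at the true window is
standardised across events to $z_e$, the symmetric Dirichlet
concentration is $\theta_e = \exp(a_0 + a_1 z_e)$, relative abundances
are Dirichlet, totals Poisson, counts multinomial. Larger $a_1 > 0$
makes high-driver events stochastically more even, hence higher expected
$H$ and $E$, without hand-tuned per-family response curves; $a_1$ is
scale-free because the driver is standardised. Defaults $a_0 = 0.5$,
$a_1 = 0.8$, 200 expected specimens. An optional trait-clustered
(functional) planting was considered and rejected: taxonomic recovery is
the primary validation surface, and the functional indices respond to
the evenness planting anyway.

What passing the simulation study does **not** show: that real
communities respond this way. The generator has no seasonality, no
taxon-specific hydraulic niches, no observation error in the biological
sampling, and its discharge comes from the same simulator under test
(internal consistency, not external validity). It demonstrates only that
*if* a monotone antecedent-flow signal of realistic strength exists at
one window, the chain identifies that window and descriptor family.

## Validation by simulation: the recovery study

The packaged experiment (`recovery_experiment()`) draws, per replicate,
a 10-year synthetic rainfall record, simulates discharge, samples 60
events, plants the signal on the cumulative negative flow change
(`sum_fall`) at the 9-day window with $a_1 = 0.8$, and runs the full
fit. Across 30 replicates the 9-day window is selected in well over 70%
and the planted driver ranks in the top two by $\Delta R^2_{adj}$ for
$H$ in well over 70%; with $a_1 = 0$ (60 replicates) no window's
selection share departs from the chance rate of 1/3 (one-sided binomial
test at $\alpha = 0.01$). The driver's rank for $H$ in this experiment
is computed directly on the $H$ model at the selected window, regardless
of the normality triage that gates the headline importance table —
otherwise the measure would be undefined in replicates where $H$
happens to fail the screen. Problem sizes (60 events, 30/60 replicates,
10-year records) were chosen as the smallest giving stable rates.

One caveat the study surfaced: in recession-dominated regimes
`sum_fall` and `q_mean` are strongly rank-correlated (≈ 0.9), so
drop-one importance necessarily splits credit between them; the planted
driver reliably reaches the top two but not always rank one. That is a
property of collinear descriptors under drop-one designs, not of the
implementation.

## Degenerate inputs and tie-breaks

* All-zero flow window: `rb` defined as 0.
* Monoculture: $E$ is NA; any model response containing NA aborts with
  an explicit message rather than silently dropping events.
* Constant response: $R^2 = 0$ convention, intercept-only fit.
* Constant series in `range_scale()`: zeros plus a `constant` flag.
* Window-selection ties: mean RMSE, then the shortest window.
* Descriptors with fewer than $k$ distinct values enter as linear terms.
* Reduced models that fail to refit during drop-one become NA cells,
  never fatal.

## Known limitations

* The hydrological model is uncalibrated by construction (ungauged
  setting); only relative temporal variation is meaningful, and
  absolute discharge magnitudes should not be interpreted.
* The CN is a single scalar; no spatial distribution, no inter-day
  moisture accounting, no snow or fog processes (relevant in paramo).
* $p_{\mathrm{eff}}$-based adjustment of $R^2$ for penalised smooths is
  a convention; alternatives would shift $R^2_{adj}$ by small amounts.
* The AR(1) attempt rarely converges at these sample sizes, so most
  fits use the event-smooth fallback — consistent with the motivating
  analysis, where no correlation structure was retained either.
* FAD1 and wFDc have competing definitions in the literature; the forms
  used here are documented above and isolated for substitution.
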