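---
title: "Halothermal-time germination modelling: methods and design notes"
author: "halott package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halothermal-time germination modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halott)
```

## The population-threshold model

Seed germination under combined temperature and salinity (osmotic) stress is
described here by a *halothermal-time* (HaloTT) model, a population-based
threshold model in the hydrotime/hydrothermal-time family. Each seed in a
population carries its own base water potential $\psi_b$ below which it
cannot germinate; across the population the thresholds are normally
distributed, $\psi_b \sim N(\psi_b(50), \sigma_{\psi_b}^2)$. At temperature
$T$ (between a base $T_b$ and a ceiling $T_c$) and ambient water potential
$\psi \le 0$, the time $t_g$ for percentile $g$ of the population to
germinate satisfies

$$\theta_{HaloTT} = (\psi_{adj} - \psi_b(g)) \, (T - T_b) \, t_g,
\qquad
\psi_{adj} = \psi - k_T \max(0, T - T_o),$$

where $\theta_{HaloTT}$ (MPa °C h) is the halothermal time constant and
$k_T$ (MPa/°C) shifts the effective threshold toward zero above the optimum
temperature $T_o$ — the mechanism by which supra-optimal temperatures
suppress germination. At a single temperature the relation collapses to the
halotime model $\theta_{Halo} = (\psi - \psi_b(g))\, t_g$ with
$\theta_{Halo} = \theta_{HaloTT} / (T - T_b)$. Applying the probit
(inverse-normal) transform linearises the model:

$$\mathrm{probit}(g) =
  \frac{\psi_{adj} - \theta_{HaloTT} / ((T - T_b)\, t_g) - \psi_b(50)}
       {\sigma_{\psi_b}},$$

so for a *known* time constant the threshold distribution's median and
spread fall out of an ordinary linear regression of $\mathrm{probit}(g)$ on
the covariate $x = \psi_{adj} - \theta/((T - T_b) t_g)$: the slope is
$1/\sigma_{\psi_b}$ and the intercept $-\psi_b(50)/\sigma_{\psi_b}$.

Two sign conventions for the supra-optimal term circulate (the shift can be
written inside the threshold or subtracted from $\psi$); we subtract it from
$\psi$ (the $\psi_{adj}$ form above), which is the reading consistent with
fitted $\psi_b(50)$ values becoming more positive above $T_o$.

## Repeated probit regression

`fitHalotime()` and `fitHalothermal()` estimate the time constant by
*repeated probit regression*: candidate values of $\theta$ are scored by the
$R^2$ of the inner linear regression, and the $\theta$ maximising $R^2$
defines the fit. Because the probit responses are fixed while only the
covariate changes with $\theta$, maximising $R^2$ is equivalent to
minimising the residual sum of squares — which is what the brute-force grid
oracle in the test suite checks. The search is deterministic: 200
log-spaced candidates spanning $[10^{-2}, 10^{5}]$ (halotime, MPa h) or
$[10^{-1}, 10^{6}]$ (halothermal, MPa °C h), refined by golden-section to a
relative tolerance of $10^{-4}$. In the joint halothermal fit, $k_T$ is
profiled out at each candidate $\theta$ by one-dimensional optimisation
(and pinned to 0 when no supra-optimal temperatures are supplied).
Candidates whose inner regression has non-positive slope are inadmissible —
a negative fitted spread would violate the model — and a fit whose *best*
candidate is inadmissible raises an error rather than returning nonsense.

### Probit points

A cumulative germination curve contributes one probit point per reached
fraction. Two conventions are implemented:

* **`percentiles = "observed"` (default).** Every distinct positive
  cumulative count level of a count-backed curve enters at its
  first-attainment time. This is the classical repeated-probit treatment of
  scored dish data, and it is the convention under which the boundary rules
  operate: a fraction of exactly 0 is dropped (its probit is undefined) and
  a fraction of exactly 1 is replaced by the small-sample correction
  $(2n-1)/(2n)$.
* **A numeric grid** (e.g. deciles `seq(0.1, 0.9, 0.1)`), intersected per
  curve with the fractions actually reached. Continuous model curves
  (from `predictTimeCourse()`, which carry no seed count) always use the
  decile grid.

The observed convention is the default because sparse treatments matter:
with ten-seed dishes and strong stress, a curve often plateaus below the
0.1 decile yet still carries information in its one or two positive counts.
Under the reference study design (three dishes of ten seeds per treatment,
daily scoring), a decile grid discards roughly three quarters of otherwise
fittable Monte-Carlo replicates at 20 °C and noticeably biases the
surviving spread estimates; the observed convention keeps them.

Percentile times are obtained by linear interpolation of the cumulative
count between bracketing observations — the classical $t_{50}$ rule
$t_i + (N/2 - n_i)(t_j - t_i)/(n_j - n_i)$, applied uniformly to every
percentile, with the interpolation anchored at $(0, 0)$ when the first
observation already exceeds the target. Percentiles never reached are
reported as `NA`; the corresponding germination *rate* is 0 with a
`reached = FALSE` flag.

## Cardinal temperatures

`estimateCardinalTemperatures()` reports both conventions side by side:

* **grid mode** — $T_o$ is the tested temperature with maximal GR50 (ties
  toward the lower temperature; a maximum at the grid edge is flagged);
* **regression mode** — GR50 is regressed on $T$ separately over the
  sub-optimal limb ($T \le T_o^{grid}$) and the supra-optimal limb; $T_b$
  and $T_c$ are the x-intercepts and the regression $T_o$ is the lines'
  intersection.

Temperatures at which the 50th percentile is never reached enter the limbs
with GR50 = 0. Under a threshold model a temperature outside $(T_b, T_c)$
*has* zero germination rate, so these zeros are genuine observations of the
limb; excluding them would leave the sub-optimal limb of a design whose
lowest tested temperature equals $T_b$ with a single point and no
regression at all. The caller can always filter rates beforehand if a
different convention is wanted.

`estimateKT()` regresses per-temperature fitted $\psi_b(50)$ values on
$(T - T_o)$ over supra-optimal temperatures; the slope is $k_T$ in MPa/°C.
(A printed unit of "MPa °C h$^{-1}$" sometimes attaches to this
coefficient in the literature; the model algebra forces MPa per °C.)

## Germination indices

Twelve classical indices are computed per dish on a daily schedule
(`day = ceiling(time_h / 24)`; the day length is configurable because model
fitting works in hours while the index literature speaks in days): GP, MGT,
GRI, GI, CVG, GE, the Timson index, MGR, SVI-I, SVI-II, T50 and the
root:shoot dry-weight ratio. Treatment summaries are replicate means ±
standard errors, and the per-dish values (not the treatment means) feed the
ANOVA, since only per-dish values provide residual degrees of freedom.

Two printed-formula ambiguities are resolved as follows. The germination
index (GI) uses descending integer weights (test length down to 1),
generalised from the usual ten-day special case to any test length. The
Timson index is implemented as the standard sum of cumulative germination
percentages over the test period — the variant whose theoretical maximum of
$100 \times \text{period}$ is attained in the all-first-day degenerate case
— because the printed alternative in parts of the index literature
duplicates the $t_{50}$ interpolation formula and cannot be a cumulative
index. Both choices are anchored by their quoted extremal properties,
which the test suite asserts.

Vigour indices use the dish mean of (conventionally three) measured
seedlings; the root:shoot ratio is the ratio of dish-mean dry weights.

## ANOVA

`anovaTwoWay()` computes the sequential (Type I) two-way decomposition from
first principles, by QR projections of the nested model sequence
$1 \to T \to T + \psi \to T \times \psi$, so the sum-of-squares identity
$SS_T + SS_\psi + SS_{T\times\psi} + SS_{res} = SS_{tot}$ is exact on
balanced designs and testable to $10^{-8}$. Single-replicate designs flag
the interaction as untestable; zero residual variance flags infinite F.
p-values are unadjusted, as is conventional for these factorial screens.
The base-R `aov()` is used in the test suite as an independent
cross-check, never as the implementation.

## The simulator

`simulateExperiment()` generates exactly the data structure the analysis
assumes: per dish, Bernoulli viability thinning, iid normal threshold
draws, halothermal germination times
$t = \theta_{HaloTT}/((\psi_{adj} - \psi_b)(T - T_b))$ (infinite outside
the thermal window or when $\psi_{adj} \le \psi_b$), multiplicative
lognormal timing noise, and cumulative counts at each observation time.

Defaults emulate the reference barley experiment: 6 temperatures (15–40 °C
by 5) × 5 water potentials (0 to −2 MPa by 0.5) × 3 dishes of 10 seeds,
24 h observations to 336 h, 95 % viability, timing-noise sd 0.15 (threshold
models place residual variation on the rate scale, hence multiplicative
noise with median 1), and the reference parameter set
`barleyHaloTTParams()`: $\psi_b(50) = -0.23$ MPa,
$\sigma_{\psi_b} = 0.21$ MPa, $\theta_{Halo} = 17.65$ MPa h at the 20 °C
optimum (so $\theta_{HaloTT} = 88.25$ MPa °C h with $T_b = 15$ °C),
$k_T = 0.104$ MPa/°C, cardinal temperatures 15/20/40 °C.

Two deliberate simplifications: seedling growth (for the vigour indices) is
a documented linear decline with $|\psi|$ and $|T - T_o|$ plus Gaussian
noise — it exercises SVI-I/II and RSR, it does not model biology — and no
seed-aging treatment is simulated.

For parameter-recovery work the simulator offers
`thresholds = "stratified"`: per-seed thresholds are the deterministic
mid-quantiles $\Phi^{-1}((i - 0.5)/n)$ of the threshold distribution, so a
finite dish is an exact discretisation of the population and a noise-free
dense design refits to the generator parameters within numerical tolerance
(the forward–inverse round trip asserted in the tests: location and spread
within 0.02 MPa, time constant within 2 %).

### What the simulator does and does not establish

Passing recovery tests on simulated data shows that the estimator inverts
the model it assumes — it says nothing about model adequacy for real dishes
(dormancy, ion-specific toxicity beyond the osmotic effect, seed aging and
scoring error are all outside the generator). One tension inherited from
the reference parameter set is worth knowing: with
$\psi_b(50) = -0.23$ MPa and $\sigma = 0.21$ MPa the model predicts
essentially no germination at $\psi \le -1$ MPa, although germination there
is reported in parts of the source literature; the defaults follow the
parameter set, and the simulated design consequently carries most of its
information at 0 and −0.5 MPa and near-optimal temperatures. For the same
reason supra-optimal halotime fits are only possible close to $T_o$
(above ≈ 22 °C the shifted threshold extinguishes the wettest treatment),
which is why the $k_T$ recovery analyses sample 20.5–22 °C rather than the
25–40 °C arm of the factorial grid.

## Numerical choices and problem sizes

* θ search: deterministic log-grid (200 points) + golden section
  (rel. tol. $10^{-4}$); $k_T$ profiled by `optimize()` on $[-0.5, 1.5]$.
* Interpolations compare fractions with a $10^{-12}$ absolute guard so
  exactly-attained counts return their observation time.
* Monte-Carlo recovery studies use 200 replicates of the factorial design
  at 20 °C (about 15 s of CPU); noise-free recovery uses one stratified
  dish of 400 seeds per treatment on a 4 h grid. These sizes give
  Monte-Carlo standard errors an order of magnitude below the quantities'
  tolerance bands.
* All randomness flows through the `seed` field of `simConfig()`; equal
  seeds give byte-identical simulations, fixtures and pipeline outputs.

## Limitations

* The estimator is the classical two-stage repeated probit regression, not
  maximum likelihood on the binomial counts; with ten-seed dishes the
  spread estimate $\hat\sigma_{\psi_b}$ inherits a modest upward
  finite-sample bias (documented by the Monte-Carlo tests), which weighted
  or likelihood-based variants would reduce at the cost of leaving the
  published estimator.
* $T_b$, $T_o$ and (optionally) $T_c$ are inputs to the joint fit, taken
  from the cardinal-temperature stage; they are not jointly estimated with
  the threshold parameters.
* The supra-optimal *thermal-time* constant is tabulated in its printed
  historical form $(T_c(g) - T_b)\,t_g$ by default; pass
  `supraForm = "conventional"` for $(T_c(g) - T)\,t_g$.
* NaCl concentrations are mapped to osmotic potential by the fixed van 't
  Hoff factor −4.4 MPa per mol/L (25 °C); no activity corrections.
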