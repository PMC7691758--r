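---
title: "Multi-numeraire appraisal: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-numeraire appraisal: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numeraire)
```

## The appraisal problem

A health-related project — a vaccination programme, a new technology, a
nutrition or environmental intervention with health effects — produces
per-period streams of three things: incremental health effects
$\Delta h_t$ (QALYs gained or DALYs averted), incremental health-care costs
$\Delta c_{ht}$, and incremental consumption costs $\Delta c_{ct}$ (negative
when the project frees up private consumption). The appraisal question is
how to weigh effects that arrive at different times, in different units, in
different countries.

The framework implemented here refuses to bundle those judgements into a
single discount rate. Instead it converts all effects, period by period,
into a common numeraire using three explicit value parameters, and then
discounts each numeraire at the one rate that matches it:

* $k_{ht}$ — the **health opportunity-cost threshold** (currency per health
  unit): the health forgone elsewhere when one unit of health-care
  expenditure is displaced. Spending $\Delta c_{ht}$ therefore displaces
  $\Delta c_{ht}/k_{ht}$ units of health.
* $k_{ct}$ — the **consumption opportunity cost** of a unit of health-care
  expenditure (dimensionless): the net production forgone per currency unit
  spent on health care.
* $V_{ht}$ — the **consumption value of health** (currency per health
  unit): the consumption a society would trade for one unit of health.
  Empirically $V_{ht} > k_{ht}$ is the norm: demand-side values exceed
  supply-side opportunity costs.

The per-period column algebra is:

$$\text{net health}_t = \Delta h_t - \Delta c_{ht}/k_{ht}, \qquad
  \text{net consumption cost}_t = \Delta c_{ct} + k_{ct}\,\Delta c_{ht},$$

$$\text{equivalent consumption}_t
  = V_{ht}\left(\Delta h_t - \frac{\Delta c_{ht}}{k_{ht}}\right)
  - \left(\Delta c_{ct} + k_{ct}\,\Delta c_{ht}\right),$$

with the equivalent **health** effect equal to the consumption effect
divided by $V_{ht}$ and the equivalent **resource** effect equal to the
health effect multiplied by $k_{ht}$. Because $V_{ht}, k_{ht} > 0$, the
three representations always share a sign period by period
(`extensive_table()` reports all of them). When a project has no
consumption-side effects, $V_{ht}$ rescales both sides of the decision and
drops out of it entirely.

Displaced expenditure in another constrained public sector $x$ is shadow
priced at $V_{xt}/k_{xt}$; absent sector-specific estimates,
`shadow_price_other_sector()` defaults to $V_{ht}/k_{ht}$, on the reasoning
that a government facing an overall expenditure constraint equalises this
ratio across sectors.

## Matched discount rates

Each numeraire has its own rate:

* **Consumption** at the Ramsey rate $r_c = \delta + \eta g_c$, pure time
  preference plus a wealth effect.
* **Health** at the revealed health time-preference rate
  $r_h = r_s - g_{k_h}$, where $r_s$ is the principal's real
  borrowing/saving rate and $g_{k_h}$ the expected threshold growth: if
  thresholds grow, future health is relatively cheaper to buy, so current
  health is relatively more valuable.
* **Health-care resources** at $r_s$ itself.

Dual rates ($r_h + g_{k_h}$ for costs in ICER reporting, $r_c - gV_h$ and
$r_c - gV_h + g_{k_h}$ in the consumption framing) fold expected parameter
growth into the discount rate instead of into the streams. They are
implemented (`dual_cost_rate()`, `dual_schedule()`, `icer_dual()`) because
ICERs remain the field's lingua franca, but the package's position is that
the extensive tables are the primary output and dual discounting is
reported only alongside them.

### Compounding conventions

`approx_subtractive` reproduces the printed small-rate arithmetic above.
`exact_multiplicative` (the default) composes the same ingredients as
growth factors — $r_h = (1+r_s)/(1+g_{k_h}) - 1$ and so on — and is what
makes the equivalences *identities*: discounting
$k_{h1}(1+g_{k_h})^{t-1}\Delta h_t$ at $r_s$ equals
$k_{h1}/(1+g_{k_h})$ times discounting $\Delta h_t$ at the exact $r_h$,
for every stream, to machine precision. Reports state the convention used.

### Anchoring dual schedules at the period-1 base

Parameter paths place their base value at $t = 1$:
$k_{ht} = k_{h1}(1+g)^{t-1}$. A flat exact dual rate applied from period 1
would therefore compare the ICER against $k_{h1}/(1+g)$ rather than the
period-1 threshold itself. Under the exact convention `dual_schedule()`
instead applies the growth adjustment from period 2 onward, giving discount
factors $(1+r)^{-t}(1+g)^{-(t-1)}$. With that anchoring,
$\mathrm{ICER} < k_{h1}$ is an exact restatement of a positive discounted
net health benefit whenever the discounted health effect is positive — the
property `icer_dual()` and the test suite rely on. Negative discounted
health effects are labelled with their cost-effectiveness-plane quadrant
rather than read as bare ratios, and the verdict is taken from the net
benefit $PV(\Delta h) - PV_{\text{dual}}(\Delta c_h)/k_{h1}$, which is
orientation-free.

### When do the CEA and BCA framings agree?

The consumption, health and resource *numeraire* present values reported by
`npv_country()` always share a sign: they are the same stream rescaled by
positive per-period factors, discounted at schedules that differ by exactly
those factors. The *net-health decision at* $r_h$ is a different value
system (thresholds and the principal's rate, not consumption values and the
Ramsey rate); it coincides with the consumption framing precisely when the
rates are mutually consistent,
$(1+r_s)/(1+g_{k_h}) = (1+r_c)/(1+gV_h)$. The randomized concordance tests
impose that consistency condition when they compare the two framings;
without it the two can genuinely disagree, which is the substantive choice
between cost-effectiveness and benefit-cost analysis, not a numerical
artefact.

### Declining term structures

With a point growth assessment the consumption schedule is flat. Persistent
uncertainty about growth, expressed as scenarios $\{(g_i, p_i)\}$, yields
certainty-equivalent discount factors
$F(t) = \sum_i p_i (1+r_i)^{-t}$ with $r_i = \delta + \eta g_i$, and
annualised term rates $R(t) = F(t)^{-1/t} - 1$. $R(t)$ starts below the
probability-weighted mean rate (Jensen), declines monotonically, and
approaches the lowest scenario rate from above — slowly:
$R(t) - r_{\min} \approx \log(1/p_{\min})/t$, so convergence checks are
run on scenario sets with balanced probabilities and a material rate
spread (two scenarios, $p \in [0.4, 0.6]$, spread of 3.5–6 percentage
points), where 90% of the gap has closed by $t = 500$. Near-degenerate
weights close the gap only at terms far beyond any appraisal horizon. The
paper-level guidance survives in code as an advisory: building a flat
point-growth schedule beyond 30 periods emits a warning suggesting a
scenario set; nothing changes silently.

### Catastrophic hazard and project risk

A per-period probability `p_cat` of a truly non-recoverable catastrophe
multiplies each discount factor by $(1-p_{cat})^t$. Only genuinely
non-recoverable events qualify, so `discount_spec()` warns above 0.1% per
period. The hazard is applied to whichever schedule the user attaches it
to via the discount specification — in `npv_country()` that is the
consumption schedule and, through the factor adjustments, the other
numeraire schedules derived from it; the choice is recorded here rather
than hidden. Project-specific macro-correlation is a user-supplied additive
premium on every forward rate (`beta_premium`, negative for countercyclical
projects); no attempt is made to estimate betas. Whether $\delta$ should be
nonzero for intergenerational projects is left as a normative toggle with
default 0.

## Country contexts, defaults and aggregation

`country_context()` bundles base parameter values, a `growth_spec()` and a
`discount_spec()`. A single consumption-growth assessment feeds every
parameter that depends on it: the Ramsey wealth effect, the growth of
$V_{ht}$ (via the income elasticity of demand for health) and the growth of
$k_{ct}$ all read `g_c` unless explicitly overridden.

Two named judgement profiles are built in. The **conservative** profile
sets $k_c = 1$ (one currency unit of health-care expenditure displaces one
unit of net production), income elasticity 1 (so $V_{ht}$ grows at $g_c$),
$\eta = 1$ (so $r_c = g_c$) and $\delta = 0$. The **alternative** profile
raises the elasticity to 1.5 and $\eta$ to 2 ($r_c = 2g_c$). When a context
file omits a judgement parameter, `load_contexts()` fills it from the named
profile and logs each fill, so every number in a report is traceable to
user input or a named default.

Because every one of these parameters is country specific — above all
$g_c$ — a multi-country project is valued as the **sum of country-specific
NPVs**, each computed in the country's own equivalent-consumption stream
and discounted at the country's own rate, never as pooled effects under a
common rate. `npv_global()` requires a single declared currency label and
refuses to sum across mismatched labels; no exchange-rate or
purchasing-power conversion is attempted.

Both the consumption-value representation of health-care costs
($V_{ht}\,\Delta c_{ht}/k_{ht}$) and the net-production representation
($k_{ct}\,\Delta c_{ht}$) appear as separate columns in the extensive
table; neither is silently substituted for the other, since they answer
different questions about the same expenditure.

## Numerical and design choices

* **Accrual timing.** Whether effects accrue at period start or end is not
  dictated by the framework; the package adopts end-of-period accrual with
  factors $(1+r)^{-t}$ for period $t$, matching the $\left(1+r_c\right)^t$
  denominators of the country-NPV formula, and reports state it.
* **Indifference.** Verdicts use the exact sign of the present value; no
  tolerance band is applied. Values are reported at full precision and
  rounding is the caller's decision.
* **Degenerate inputs.** A zero or negative threshold is an error, not an
  infinite opportunity cost; scenario probabilities must be positive and
  sum to 1 (tolerance $10^{-8}$); forward rates must stay above $-100\%$
  after any risk adjustment.
* **Serialisation.** CSV output writes 17 significant digits so that
  parse(render(x)) reproduces every number exactly.

## What the synthetic projects emulate — and what they do not

`generate_fixture()` draws toy projects with per-period health effects in
$[-5, 20]$ health units, health-care costs in $[-2000, 10000]$ and
consumption costs in $[-1000, 2000]$ currency units, thresholds in
$[500, 5000]$ with $V_{h}$ drawn 1.5–4 times the threshold, and growth
rates in $[0, 5\%]$ — magnitudes typical of programme-level appraisals in
low- and middle-income settings, deliberately spanning all four
cost-effectiveness quadrants. Expected NPVs accompanying each fixture are
computed by a straight-line scalar loop over the defining formulas
(`expected.json`), sharing no arithmetic with the package's vectorised
paths. Passing against these fixtures demonstrates internal correctness of
the accounting and discounting algebra; it says nothing about the realism
of any particular country's $k_{ht}$, $V_{ht}$ or growth expectations,
which are empirical inputs the user must supply and defend. Real effect
streams are also serially correlated and estimated with uncertainty;
fixtures are i.i.d. draws and carry no probabilistic sensitivity analysis
(out of scope here).

Test and check problem sizes — horizons up to 10 periods, 1000-case
randomized sweeps, 100 seeded fixtures, 500-period term structures — were
chosen so the full suite characterises the invariants well while running
in seconds.

## Known limitations

* No estimation: $k_{ht}$, $k_{ct}$, $V_{ht}$ and $\eta$ are inputs, not
  outputs. The package will not derive them from mortality, expenditure or
  stated-preference data.
* No currency conversion, no equity weighting across beneficiaries or
  countries (the global NPV is an unweighted sum), no sub-annual periods.
* Project risk enters only as a user-supplied additive premium; no CCAPM
  beta estimation, no rare-disaster calibration.
* ICERs are undefined when the discounted health effect is zero; the
  error message directs users to net-benefit reporting, which is always
  defined.
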