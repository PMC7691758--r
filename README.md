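# numeraire

Multi-numeraire appraisal of health-related projects over time.

Decision makers appraising health projects — ministries of health, global
funders, HTA bodies — face streams of effects that arrive in different
units at different times: health gained (QALYs gained or DALYs averted),
health-care costs, and consumption costs, often across several countries.
The common shortcut is to bury the judgements about how these trade off
into one discount rate. `numeraire` implements the alternative: convert
every effect, period by period, into an explicit common numeraire, then
discount each numeraire at the one rate that matches it, and report the
whole accounting extensively so each judgement stays visible and revisable.

## The model

Three per-period value parameters do the conversion:

- `k_ht` — health opportunity-cost threshold (currency / health unit):
  spending `Δc_ht` on this project displaces `Δc_ht / k_ht` health
  elsewhere in the system;
- `k_ct` — consumption (net production) opportunity cost per unit of
  health-care expenditure (dimensionless, conservative default 1);
- `V_ht` — consumption value of a health unit (currency / health unit),
  typically above `k_ht`.

The period-`t` net effect in the consumption numeraire is

```
V_ht (Δh_t − Δc_ht / k_ht) − (Δc_ct + k_ct Δc_ht)
```

with the health-numeraire effect equal to this divided by `V_ht`, and the
resource-numeraire effect equal to the health effect times `k_ht`.
Matched discounting: consumption streams at the Ramsey rate
`r_c = δ + η g_c`; health streams at the revealed health rate
`r_h = r_s − gk_h` (the principal's real borrowing rate net of threshold
growth); resource streams at `r_s`. Dual rates (`r_h + gk_h`, etc.) are
provided for ICER reporting but the extensive tables are the primary
output. Growth uncertainty expressed as scenarios `{(g_i, p_i)}` yields a
declining certainty-equivalent term structure
`R(t) = [Σ p_i (1+r_i)^(−t)]^(−1/t) − 1`; catastrophic hazards and signed
project risk premia overlay any schedule.

A multi-country project is valued as the **sum of country-specific NPVs**,
each country's equivalent-consumption stream discounted at that country's
own rate — never pooled effects under a common rate.

## Worked example

A three-year immunisation programme: large up-front delivery costs, health
benefits and out-of-pocket savings that build over time, appraised against
a threshold of 500 per DALY averted, a consumption value of health of
1500, 4% consumption growth (conservative profile, so `r_c = g_c`), 2%
threshold growth and a 5% principal's rate.

```r
library(numeraire)

vacc <- effect_stream("ZMB",
  delta_h   = c(120, 450, 600),           # DALYs averted
  delta_c_h = c(250000, 40000, 20000),    # delivery + maintenance costs
  delta_c_c = c(15000, -5000, -20000),    # out-of-pocket costs then savings
  health_metric = "DALY_averted")

ctx <- country_context("ZMB",
  k_h1 = 500, V_h1 = 1500, k_c1 = 1,
  growth   = growth_spec(g_c = 0.04, gk_h = 0.02),
  discount = discount_spec(delta = 0, eta = 1, r_s = 0.05))

res <- npv_country(vacc, ctx)
res
#> <appraisal_result> country ZMB (INT$, exact_multiplicative discounting)
#>   NPV (consumption numeraire): 507675 INT$
#>   PV equivalent health: 338.45; PV equivalent resources: 169225
#>   net-health decision: adopt (PV net health 496.279)
#>   ICER: 272.61 vs k_h1 = 500 [NE (more effective, more costly)] -> adopt
#>   (extensive table: 3 periods; effects accrue end-of-period)
```

The NPV of 507,675 is the discounted sum of the per-period
consumption-equivalent effects; the per-numeraire PVs are the same
quantity expressed in health units (338 DALYs) and health-care resources
(169,225), and they always share a sign. The ICER of 272.61 per DALY
averted sits below the period-1 threshold of 500, agreeing with the
net-health verdict. The full period-by-period accounting — including the
first year's negative net effect, outweighed later — prints with
`render_extensive_report(res, format = "text")`:

```
-- Net effects per numeraire --
 t eq_consumption eq_health eq_resource
 1        -835000  -556.667     -278333
 2         543047   348.107      177535
 3         909432   560.547      291597

Net present value (consumption numeraire): 507675 INT$
```

Multi-country projects combine `load_streams()` (CSV of
`country,t,delta_h,delta_c_h,delta_c_c`), `load_contexts()` (YAML/JSON of
per-country parameters, with omitted judgement parameters filled from
named conservative/alternative profiles and each fill logged) and
`npv_global()`, which sums country NPVs under a declared common currency.
`generate_fixture()` produces seeded toy projects whose expected NPVs are
computed by an independent straight-line loop, and
`inst/cli/appraise.R` wraps it all for the shell
(`evaluate`, `rates`, `report`, `fixtures` subcommands).

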