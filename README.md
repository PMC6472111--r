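# bmslca

Carbon-footprint analysis of powdered breastmilk substitutes (BMS, infant
formula for 0–6 months) compared with breastfeeding, as a tested,
configuration-driven R pipeline.

## The problem and who this is for

Producing and consuming infant formula has a climate cost: raw milk
production (enteric methane above all), drying and processing energy,
packaging, transport, and the boiling of water to sterilise bottles and
prepare feeds. Breastfeeding has a climate cost too — the additional food
(~500 kcal/day) a breastfeeding mother needs. This package implements a
cradle-to-bottle life-cycle model that quantifies both sides per a common
functional unit (1 kg of BMS powder at 21.7 kJ/g, in kg CO2-equivalents,
GWP100) for four production countries (New Zealand, USA, Brazil, France)
and four consumption countries (UK, China, Brazil, Vietnam). It is aimed at
food-systems LCA practitioners and at anyone who wants to probe the
sensitivity of such comparisons to allocation choices, sterilisation
practice, packaging, GWP characterisation factors, land-use change and
recipe formulation.

## The model in brief

* **CFP_Prod** (cradle to factory gate, per kg powder):
  `raw milk + vegetable oils + processing + packaging + transport`, where
  the raw-milk stage is `EF_milk × m_alloc × Π 1/(1−w_i)` — the emission
  factor per kg energy-corrected milk times the milk mass allocated to the
  powder through the dairy co-product tree (13.7 kg in, 6.6 kg allocated
  under the default dry-mass allocation) times the chain-waste multiplier.
  Co-product allocation (cream, cheese curd, lactose permeate) composes
  multiplicatively along the process tree under one of four bases: dry
  mass, fat+protein, energy content, economic value.
* **CFP_Cons** (cradle to bottle): CFP_Prod + retail transport + bottle
  manufacture + in-home sterilisation (boiling 54 bottles per kg powder in
  batches of six in 5 L water) + preparation (0.13 L heated per bottle),
  through country-specific stove profiles.
* **CFP_BF**: the country's average-diet footprint per MJ (production,
  inflated by household waste, plus cooking at 1.3 MJ heat per kg food)
  times 385/21 ≈ 18 MJ of food per kg BMS replaced, times `1 − BMS waste`.
* **Uncertainty**: Monte Carlo over the configured parameter distributions
  (normal/lognormal CVs, triangular ranges), reported as mean, SD, CV, 95%
  interval and the exceedance probability P(CFP_Cons > CFP_BF).

See the methods vignette (`vignettes/methods.Rmd`) for the full model,
calibration policy and design decisions.

## Worked example

```r
library(bmslca)
scens <- default_scenarios()

cfp_production(scens[["New Zealand"]])
#> Scenario: New Zealand
#> Allocation basis: dry_mass
#> raw_milk        7.1 kg CO2e/kg BMS
#> vegetable_oils  0.52 kg CO2e/kg BMS
#> processing      0.72 kg CO2e/kg BMS
#> packaging       0.26 kg CO2e/kg BMS
#> transport       0.57 kg CO2e/kg BMS
#> Total: 9.2 kg CO2e/kg BMS
```

Raw milk dominates (7.1 of 9.2, a 78% share; across the four production
countries the share spans 68–82%). China consumes BMS produced in New
Zealand; adding the consumption phase and comparing with breastfeeding:

```r
cons <- cfp_consumption(scens[["China"]], cfp_production(scens[["New Zealand"]]))
bf   <- cfp_breastfeeding(scens[["China"]])
compare_footprints(cons, bf)
#> CFP_Cons 13.84 vs CFP_BF 6.50 kg CO2e/kg BMS
#> difference 7.34 (ratio BF/Cons 0.47)

monte_carlo(scens[["China"]], n = 10000, seed = 1, mode = "comparison")
#> Monte Carlo (comparison), n = 10000, seed = 1, basis = dry_mass, GWP = AR4
#>      output point   mean    sd     cv ci95_low ci95_high
#>    cfp_cons 13.84 13.850 1.670 0.1206   10.582    17.108
#>      cfp_bf  6.50  6.508 1.206 0.1853    4.481     9.104
#>  difference  7.34  7.341 2.056 0.2801    3.235    11.341
#> P(CFP_Cons > CFP_BF) = 0.9997
```

Feeding BMS in China carries roughly twice the footprint of the
breastfeeding equivalent (13.84 vs 6.50 kg CO2e per kg powder: the
sterilisation stage alone, 3.8 kg CO2e, exceeds half of the breastfeeding
total), and the sign of the difference survives parameter uncertainty in
99.97% of draws. Sensitivity switches — allocation bases, steam or no
sterilisation, 100% tin-can or bag-in-box packaging, AR5 / AR5-feedback
characterisation, land-use change, vitamin and mineral additions — are one
call away:

```r
oat_sensitivity(scens[["New Zealand"]], parameters = "raw_milk_ef",
                target = "production")
#>     parameter pct_change_low pct_change_high
#> 1 raw_milk_ef      -7.752327        7.752327

cfp_consumption(scens[["China"]],
                cfp_production(scenario_variant(scens[["New Zealand"]],
                                                "allocation_fat_protein")))
```

`run_pipeline(run_manifest(seed = 1, n = 10000))` executes all three stages
for every packaged country and `render_tables()` / `figure_series()` emit
the result tables (CSV and formatted text) and the comparison figure data.

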