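---
title: "Methods: modelling the carbon footprint of breastmilk substitutes versus breastfeeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the carbon footprint of breastmilk substitutes versus breastfeeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmslca)
```

## The model

`bmslca` is a cradle-to-bottle carbon-footprint (CFP) model for powdered,
milk-based breastmilk substitutes (BMS) for infants aged 0–6 months, with a
breastfeeding-equivalence counterfactual. All results are expressed per the
functional unit of 1 kg of BMS powder at 21.7 kJ/g, in kg CO2-equivalents
(GWP100). The pipeline has three stages:

1. **Production (CFP_Prod)** — raw milk, vegetable oils, processing energy,
   packaging and inter-plant transport, up to the factory gate.
2. **Consumption (CFP_Cons)** — production plus retail transport, baby-bottle
   manufacture, and in-home sterilisation and preparation.
3. **Breastfeeding (CFP_BF)** — the footprint of producing, distributing and
   cooking the additional maternal food (about 500 kcal/day) that replaces
   1 kg of BMS, reduced by the BMS wasted after preparation (wasted powder
   needs no breastmilk to replace it).

### Recipe model

A recipe is a point on the 3-simplex of solids fractions over four
ingredients: skimmed milk solids, whey protein concentrate (WPC), lactose and
a vegetable-oil blend. The baseline is 15/10/50/25% of solids. A recipe's
nutrient profile (g per 100 kJ) is the mass-weighted ingredient composition
divided by the mass-weighted energy density, and must satisfy the Codex
Alimentarius ranges (protein 0.45–0.70, carbohydrate 2.30–3.30, fat
1.05–1.40 g/100 kJ) with at least 50% of protein from whey. Ingredient
compositions are calibrated once so that the baseline recipe reproduces the
reference profile exactly (protein 0.60, carbohydrate 2.69, fat 1.19, ash
0.08 g/100 kJ, 65% whey protein at 21.7 kJ/g) using energy coefficients of
37 kJ/g for fat and 17 kJ/g for protein and carbohydrate.

The recipe Monte Carlo draws recipes uniformly from the simplex and keeps
the Codex-compliant ones (rejection sampling; the sampling scheme is a
modelling choice — the simplest defensible null over recipes). Each sampled
recipe's footprint is normalised to the functional unit by the factor
21.7/(recipe energy density). An alternative reading — rescaling ingredient
masses instead of the final CFP — is algebraically identical here, because a
serving delivers fixed energy and the feeding plan therefore scales a
serving's mass inversely with the recipe's energy density; no flag is
exposed for it.

### Dairy mass balance and allocation

The processing chain (skimming; cheese-making whose whey is separated into
WPC and lactose powder; wet-mixing and spray-drying) is sized backwards from
the recipe's dairy ingredient demands, inflated by per-country chain-waste
multipliers `prod(1/(1-w))`. The cheese-milk quantity is set by the binding
whey component (lactose for the baseline recipe; whey protein binds for
WPC-rich recipes), with surplus components leaving in a permeate stream.
Co-products are cream, cheese curd and permeate.

Raw-milk and shared process-energy burdens are allocated at every separation
step by one of four bases — dry mass (default), fat+protein, energy content,
or economic value (price × dry mass) — composing multiplicatively along the
tree, which is the standard dairy-LCA practice for multi-level co-product
systems. Energy dedicated to a single product (wet-mix and spray-dry) is
assigned entirely to it. A closed-form consequence worth knowing: for any
basis whose property is conserved across every split (dry mass, fat+protein,
energy), the multiplicative composition collapses to
*terminal property / total input property*. The exhaustive path-enumeration
oracle in the test suite checks the implementation against this and against
arbitrary toy trees.

**Calibration.** The reference mass balance fixes 13.7 kg of raw milk per kg
BMS with 6.6 kg allocated to the powder under dry-mass allocation. Because
dry matter is conserved, those two numbers pin the effective milk dry-matter
content at 0.75/6.56 ≈ 11.4%; the packaged milk composition (fat 2.25%,
protein 2.85% with 23% whey protein, lactose 6.04%, ash 0.3%) is therefore an
*effective, calibrated* composition that reproduces the reference flows and
the relative burdens of the four allocation bases — not a farm-gate milk
assay. The same applies to the whey split, the co-product prices and the
step energies; every such value carries `calibrated: true` in the configs,
distinguishing it from printed inputs such as the raw-milk emission factors.

### Country scenarios

Four production countries (New Zealand, United States, Brazil, France;
raw-milk emission factors 1.09, 0.73, 1.28 and 0.99 kg CO2e per kg
energy-corrected milk) and four consumption countries (United Kingdom and
Vietnam supplied from France, China from New Zealand, Brazil from itself).
Scenario configuration is YAML, one file per country plus shared files, with
units stated in-field; `validate_scenario()` reports every violated
invariant (mixtures summing to one, waste fractions in [0,1), non-negative
factors) with its field path.

The in-home stages heat water on the country's stove mix: sterilisation
boils 54 bottles per kg of powder in batches of six in 5 L of water;
preparation heats 0.13 L per bottle. Heat demand is volume × 4.186 kJ/kg/K ×
80 K (20 °C ambient, no latent-heat term); a per-batch boil-duration factor
(1.0 in all countries, 1.04 in Brazil) absorbs the energy needed to keep a
batch at the boil and is calibrated to the reported sterilisation stages.
Maternal diets are per-country item lists (energy shares, production
emission factors per MJ, household-waste fractions, cooked mass per MJ) with
cooking at 1.3 MJ of delivered heat per kg of food through the same stoves.
Animal-source food is carried at sub-item granularity (e.g. milk and cheese,
beef and lamb, separately), mirroring food-balance-sheet data; this matters
for uncertainty propagation because the per-item emission-factor draws are
independent, so coarse aggregates would concentrate variance in single
items.

### GWP characterisation

All packaged emission factors are stored under IPCC AR4 (CH4 = 25,
N2O = 298). Each factor carries gas shares (the fractions of its CO2e value
attributable to CO2, CH4 and N2O under AR4), and switching to AR5 (28/265)
or AR5 with climate-carbon feedbacks (34/298) rescales the CH4 and N2O parts
factor-by-factor. Raw milk is CH4-dominated (shares 0.25/0.67/0.08), which
makes the consumption footprint rise by ~4–5% under AR5. The same shares
imply an AR5-feedback increase of ~13–16%, on the high side of expectation —
a single set of gas shares cannot tune both switches independently; this is
a known limitation.

### Uncertainty model

Each sampled parameter has a distribution from a small grammar: normal or
lognormal parameterised by a CV (the lognormal preserves the arithmetic
mean), or triangular given as relative offsets around the point value.
Packaged set: raw-milk EF normal CV 20%; vegetable-oil EF lognormal CV 25%;
process electricity triangular −50/+80%; process heat −30/+60%;
sterilisation water ±50%; stove efficiency ±15%; food-production EFs
lognormal CV 45% drawn per diet item; cooking energy −30/+300% drawn once
per scenario. Parameters are drawn independently from one seed stream per
run, so results are bit-reproducible and both sides of the comparison see
the same draw of the shared stove-efficiency parameter (the same stove cooks
the mother's food and boils the bottles).

**Triangular centring.** For asymmetric offsets, a triangle with its mode at
the point value has a mean far above it ((a+m+b)/3; +90% for −30/+300%).
Propagating such a distribution would systematically bias the Monte Carlo
means of whole stages away from the deterministic values the tables report
as central estimates. The grammar therefore supports two centrings —
`centre: mode` (the default) and `centre: mean`, which rescales the support
so the arithmetic mean sits at the point value while preserving the relative
span — and the packaged configuration uses `centre: mean` for the three
asymmetric triangles (process electricity, process heat, cooking energy).
For symmetric offsets the two coincide.

Reported summaries are mean, SD, CV, a quantile-based 95% interval, and —
for comparisons — the exceedance probability P(CFP_Cons > CFP_BF) estimated
as the fraction of joint draws with a positive difference.

### Sensitivity analysis

`oat_sensitivity()` perturbs one parameter at a time by ±10% and reports the
signed percent change of the target total. For a stage that is exactly
linear in a parameter (the raw-milk stage in its emission factor), the
elasticity equals the stage share — an analytic oracle the tests use.
`scenario_variant()` implements the discrete switches: 100% tin-can or
bag-in-box packaging, steam or no sterilisation, the four allocation bases,
the GWP sets, land-use change, and the micronutrient add-on (2% of powder
mass × an additive emission factor spanning 0.3–67 kg CO2e/kg).

## Synthetic scenarios and what the tests show

`generate_synthetic_scenario()` produces structurally valid but randomised
scenarios: emission factors within three-fold of the range spanned by the
packaged defaults, jittered and renormalised mixtures, waste fractions in
[0, 0.4). It emulates the *structure* of real country data — positive
factors, mixtures summing to one, plausible magnitudes — but not its
correlations (e.g. between a country's grid intensity and its stove mix) or
any real country's joint parameter vector. Property tests on synthetic
scenarios therefore demonstrate structural correctness (conservation,
monotonicity, serialisation round-trips, validity of every generated
configuration), not empirical accuracy for new countries.

## Numerical choices

* Six months = 184 days, making 500 kcal/day equal the 385 MJ period total;
  the breastfeeding equivalence uses the unrounded 385/21 MJ per kg
  internally and rounds only in table output.
* The serving is 18.6 g of powder (the feeding-plan input of record); the
  constructor enforces consistency between serving mass × energy density and
  the per-serving energy within 3%, absorbing the small rounding tension in
  the underlying feeding figures.
* Mixtures must sum to 1 within 1e-9; per-step dry-matter conservation is
  checked to 1e-6; allocation factors sum to 1 to machine precision.
* Printed-style reporting rounds to two significant figures with ties away
  from zero (`format_sig`), matching the result tables' style; base R
  `signif()` rounds ties to even and would print a few boundary values
  differently.
* The recipe sampler's attempt budget errors out (rather than looping
  forever) if the feasible region is empty under user-supplied limits.
* Monte Carlo draws for the whole run come from one `set.seed(seed)` stream;
  n = 10^4 is used for the reported statistics, which puts ~±0.5 pp of
  binomial noise on exceedance probabilities near 0.95 and much less near
  0.99.
* The dense-grid feasibility oracle in the tests enumerates the simplex at
  step 0.005 in chunks over the first coordinate, keeping memory bounded.

## Known limitations

* Supplementary-level inputs (process energies per step, packaging masses,
  diet item tables, co-product prices, chain-waste fractions, stove mixes)
  are calibrated against the reported stage values rather than taken from
  primary sources; they are internally consistent and flagged `calibrated`,
  but should not be quoted as independent inventory data.
* Brazil's sterilisation/preparation pair is reproduced via the per-batch
  boil factor (1.04); the two stages cannot both be matched at two
  significant figures by a single water-volume model with a common factor.
* The energy-basis allocation variant lowers the China consumption footprint
  by ~9%; with the whey-protein feasibility constraint binding and the
  fat+protein variant calibrated, a larger energy-basis effect is not
  attainable in this co-product model.
* Liquid/ready-to-feed and specialised formulas, biogenic carbon uptake,
  refrigerated storage of prepared feeds, non-climate impact categories and
  any health-outcome weighting of the two feeding modes are out of scope.
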