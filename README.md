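# waxtherm

Biophysical heat-balance modelling of small-passerine thermal energetics,
parameterised for the common waxbill (*Estrilda astrild*, 7–9 g), a
subtropical finch that has established invasive populations in climates far
colder than its native range. Whether such a bird can persist somewhere is
ultimately an energy question, and answering it mechanistically requires a
model of what thermoregulation costs. `waxtherm` is for ecophysiologists and
invasion ecologists who want that model as tested, inspectable R code:
predicted metabolic-rate curves and thermoneutral-zone bounds to set against
respirometry, multi-day energy expenditure to set against feeding-trial
calorimetry, and a sensitivity analysis that says which traits the
predictions actually hinge on.

## The model

At the core is the steady-state balance for a homeothermic endotherm. At air
temperature $T_a$ and regulated body temperature $T_b$, the required
metabolic rate solves

$$ MR \;=\; q_{dry}(T_b, T_a) \;+\; q_{resp}(MR) \;+\; q_{cut}, $$

where $q_{dry}$ is conduction through the dorsal and ventral feather coats
(radial shells on the volume-equivalent sphere, coat conductivity
$k_{eff} = k_{air} + (k_{keratin} - k_{air}) f_v$ from the fibre volume
fraction) coupled to convection ($Nu = 2 + 0.6\,Re^{1/2}Pr^{1/3}$) and
longwave radiation at the coat surface; $q_{resp}$ is respiratory
evaporation tied to oxygen demand (linear in $MR$); and $q_{cut}$ is
cutaneous evaporation from the 1 % wet skin fraction. Solutions are clamped
at the resting floor (BMR at night, RMR by day) and a thermoregulatory
cascade handles both ends: ptiloerection scenarios (+35 %, +75 %, +200 %, or
depth = feather length) on the cold side, body-temperature elevation in
0.25 °C steps and then panting (up to 15× ventilation) on the hot side.

On top of the solver: chamber ramps with second-derivative detection of the
lower critical temperature; 73-hour expenditure simulations against net
energy intake ($NEI = 0.83\,(E_{food} - E_{excreta})$, fat at 39.5 kJ/g) and
time-energy budgets; origin-forced regression comparison with AIC ranking;
Latin-hypercube sampling over the nine trait ranges with boosted-tree
relative influence; and synthetic-data generators (cohorts, respirometry,
feeding trials, temperature logs) so the entire pipeline runs and is tested
without any external download.

## Worked example

```r
library(waxtherm)
mod <- waxbill_model(physiology_night = night_physiology(bmr_W = 0.20))
summary(mod)
#> Biophysical heat-balance model
#>   body: 7.99 g, density 875 kg/m3, shape ratio <= 3.0
#>   coat: depth 2.0/2.5 mm, length 16.1/14.1 mm (dorsal/ventral),
#>         fibre 0.030 mm, 50 /mm2, k = 0.209 W/mK
#>   physiology: Tb 39.1 C night / 41.6 C day, BMR 0.20 W, RMR 0.37 W
#>   ptiloerection levels: none, p35, p75, p200, full
#>
#> Chamber ramp (p200): lower critical temperature 28.0 C; plateau 0.200 W

predict(mod, data.frame(air_temp_C = c(10, 15, 21, 28, 35)))
#>   air_temp_C metabolic_rate_W scenario_used regulated_flag
#> 1         10            0.279          full    cold-stress
#> 2         15            0.237          full    cold-stress
#> 3         21            0.200          full  thermoneutral
#> 4         28            0.200          full  thermoneutral
#> 5         35            0.200          none    heat-stress
```

Reading this: below the thermoneutral zone the bird fluffs to maximum
insulation and still must burn above basal (0.28 W at 10 °C versus the
0.20 W summer BMR); from ~28 °C the curve sits on the basal plateau — that
kink is the lower critical temperature; by 35 °C the cascade has flattened
the coat and is shedding heat.

The 73-hour trial at its recorded ~21 °C, with full ptiloerection allowed at
night and autumn physiology (BMR 0.17 W, RMR 0.37 W):

```r
pars <- load_parameters()   # packaged waxbill trait set
simulate_ee(rep(21, 73), pars$morphology, pars$physiology_night,
            night_scenarios = "full")$total_kJ
#> [1] 100.3771
time_energy_budget(0.17)    # classical 2xBMR activity budget, same hours
#> [1] 69.156
```

The biophysical prediction (~100 kJ) sits far above the time-energy budget
(~69 kJ) because at 21 °C — below this species' TNZ — thermoregulation costs
are real and the activity-multiplier method has no term for them.

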