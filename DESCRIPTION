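Package: waxtherm
Title: Biophysical Heat-Balance Modelling of Small Passerine Thermal Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state endotherm heat-balance model for small passerine birds,
    parameterised for the common waxbill (Estrilda astrild). Computes the metabolic
    rate required for homeothermy from body geometry, plumage insulation under
    ptiloerection scenarios, convective, radiative and evaporative exchange, and a
    thermoregulatory cascade (ptiloerection, body-temperature elevation, panting).
    Simulates metabolic-chamber temperature ramps to locate the lower critical
    temperature of the thermoneutral zone, predicts multi-day energy expenditure
    against feeding-trial calorimetry and time-energy budgets, and ranks parameter
    influence by Latin-hypercube sampling with boosted regression trees. Includes
    synthetic-data generators for cohorts, respirometry curves, feeding trials and
    temperature logs so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lhs,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
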