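# Common-waxbill (Estrilda astrild) trait set for the heat-balance model.
# Morphology from museum-specimen measurements; physiology from captive-bird
# respirometry. Units noted per key.
AMASS: 7.99            # body mass, g (cohort mean after the feeding trial)
TC: 39.1               # night core body temperature, C
TC_DAY: 41.6           # daytime core body temperature, C
TC_MAX: 44.0           # maximum tolerated core temperature, C
TB_INC: 0.25           # heat-stress body-temperature increment, C
SHAPE_B_MAX: 3.0       # maximum body length:width ratio (prolate ellipsoid)
ANDENS: 875.0          # whole-body density, kg/m3
FAT_PCT: 4.0           # body fat, %
DHAIR: 0.03            # feather fibre diameter, mm
LHAIR_DORSAL: 16.1     # feather length, mm
LHAIR_VENTRAL: 14.1
ZFUR_DORSAL: 2.0       # resting feather-layer depth, mm
ZFUR_VENTRAL: 2.5
RHO: 50.0              # feather fibre density, 1/mm2
KHAIR: 0.209           # feather keratin conductivity, W/mK
QBASAL: 0.17           # basal metabolic rate (autumn, night), W
QBASAL_SUMMER: 0.20    # basal metabolic rate (summer; TNZ protocol), W
RMR: 0.37              # daytime resting metabolic rate, W
O2_EXTRACTION_PCT: 25.0
BREATH_OFFSET_C: 5.0   # expired air temperature above ambient, C
WETSKIN_PCT: 1.0
PANT_MAX: 15.0
PANT_MULT: 1.0         # BMR multiplier at maximum panting
DIGESTION_COEF: 0.83
LW_DEPTH_FRAC: 0.9     # fractional coat depth of longwave exchange
EMISSIVITY: 0.95
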