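# Default daily nutrient reference for an average adult.
#
# These are package defaults in the spirit of EU/EFSA adult reference
# values; they are NOT the (unpublished) reference set behind any specific
# national study. Supply your own file for population-specific work.
#
# Units: protein/fiber/satfat/sugar_added in g/day; Ca/Fe/Mg/K/Na/vitC/vitE
# in mg/day; vitA in ug retinol equivalents/day.
#
# Maxima for saturated fat and added sugar are 10% of the energy target
# (2228 kcal: 0.10 * 2228 / 9 kcal per g fat, 0.10 * 2228 / 4 kcal per g
# sugar); Na is the EFSA safe intake.
version: 1
energy_target_kcal: 2228
rv:
  protein: 50
  fiber: 25
  Ca: 800
  Fe: 14
  Mg: 375
  K: 3500
  vitA: 800
  vitC: 80
  vitE: 12
mv:
  satfat: 24.8
  sugar_added: 55.7
  Na: 2000
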