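# Category-conditioned sampling ranges for the synthetic food database.
#
# One block per food category. Each field is a [min, max] range sampled
# uniformly per product. Ranges are order-of-magnitude realistic for
# European retail foods (composition per gram of product as purchased;
# legumes on a dry basis; beverages include fortified plant drinks and
# sugared soft drinks). Units: energy kcal/g; protein, fiber, satfat,
# sugar_added g/g; Ca, Fe, Mg, K, Na, vitC, vitE mg/g; vitA ug/g; price
# EUR/kg; ghg kg CO2eq/kg (cradle to consumption).
version: 1
animal_categories: [red_meat, white_meat, fish, eggs, dairy]
categories:
  vegetables:
    energy_kcal_per_g: [0.2, 0.5]
    price_eur_per_kg: [1.0, 3.0]
    ghg_kgco2e_per_kg: [0.3, 1.5]
    nutrients:
      protein: [0.01, 0.03]
      fiber: [0.02, 0.04]
      Ca: [0.3, 1.5]
      Fe: [0.005, 0.025]
      Mg: [0.1, 0.3]
      K: [2.0, 4.0]
      vitA: [0.5, 6.0]
      vitC: [0.2, 0.9]
      vitE: [0.005, 0.02]
      satfat: [0.0, 0.002]
      sugar_added: [0.0, 0.0]
      Na: [0.1, 0.6]
  grains:
    energy_kcal_per_g: [2.5, 3.7]
    price_eur_per_kg: [0.8, 2.5]
    ghg_kgco2e_per_kg: [0.6, 1.8]
    nutrients:
      protein: [0.08, 0.13]
      fiber: [0.03, 0.1]
      Ca: [0.1, 0.4]
      Fe: [0.01, 0.035]
      Mg: [0.3, 1.2]
      K: [1.0, 3.0]
      vitA: [0.0, 0.0]
      vitC: [0.0, 0.0]
      vitE: [0.002, 0.01]
      satfat: [0.002, 0.01]
      sugar_added: [0.0, 0.05]
      Na: [0.5, 4.0]
  dairy:
    energy_kcal_per_g: [0.4, 1.2]
    price_eur_per_kg: [0.9, 3.0]
    ghg_kgco2e_per_kg: [1.3, 3.0]
    nutrients:
      protein: [0.03, 0.08]
      fiber: [0.0, 0.0]
      Ca: [1.1, 1.6]
      Fe: [0.0005, 0.002]
      Mg: [0.1, 0.15]
      K: [1.4, 1.8]
      vitA: [0.3, 0.6]
      vitC: [0.0, 0.02]
      vitE: [0.0005, 0.002]
      satfat: [0.01, 0.03]
      sugar_added: [0.0, 0.05]
      Na: [0.4, 0.7]
  legumes:
    energy_kcal_per_g: [3.0, 3.6]
    price_eur_per_kg: [1.5, 3.5]
    ghg_kgco2e_per_kg: [0.5, 1.5]
    nutrients:
      protein: [0.2, 0.26]
      fiber: [0.12, 0.2]
      Ca: [0.8, 2.4]
      Fe: [0.05, 0.08]
      Mg: [1.0, 1.8]
      K: [8.0, 14.0]
      vitA: [0.0, 0.1]
      vitC: [0.0, 0.05]
      vitE: [0.005, 0.02]
      satfat: [0.001, 0.01]
      sugar_added: [0.0, 0.0]
      Na: [0.01, 0.1]
  fruits:
    energy_kcal_per_g: [0.3, 0.9]
    price_eur_per_kg: [1.0, 3.0]
    ghg_kgco2e_per_kg: [0.3, 1.1]
    nutrients:
      protein: [0.005, 0.015]
      fiber: [0.015, 0.035]
      Ca: [0.05, 0.4]
      Fe: [0.002, 0.006]
      Mg: [0.08, 0.3]
      K: [1.0, 3.5]
      vitA: [0.1, 1.0]
      vitC: [0.05, 0.6]
      vitE: [0.002, 0.01]
      satfat: [0.0, 0.0]
      sugar_added: [0.0, 0.0]
      Na: [0.0, 0.05]
  red_meat:
    energy_kcal_per_g: [1.5, 2.8]
    price_eur_per_kg: [7.0, 14.0]
    ghg_kgco2e_per_kg: [15.0, 30.0]
    nutrients:
      protein: [0.17, 0.22]
      fiber: [0.0, 0.0]
      Ca: [0.05, 0.15]
      Fe: [0.015, 0.035]
      Mg: [0.18, 0.25]
      K: [3.0, 3.7]
      vitA: [0.0, 0.1]
      vitC: [0.0, 0.0]
      vitE: [0.002, 0.006]
      satfat: [0.03, 0.09]
      sugar_added: [0.0, 0.0]
      Na: [0.5, 0.9]
  fish:
    energy_kcal_per_g: [0.9, 2.0]
    price_eur_per_kg: [6.0, 16.0]
    ghg_kgco2e_per_kg: [3.0, 12.0]
    nutrients:
      protein: [0.16, 0.24]
      fiber: [0.0, 0.0]
      Ca: [0.1, 0.4]
      Fe: [0.005, 0.02]
      Mg: [0.25, 0.35]
      K: [2.8, 4.0]
      vitA: [0.1, 0.5]
      vitC: [0.0, 0.0]
      vitE: [0.005, 0.02]
      satfat: [0.005, 0.03]
      sugar_added: [0.0, 0.0]
      Na: [0.8, 1.2]
  oils:
    energy_kcal_per_g: [8.8, 9.0]
    price_eur_per_kg: [1.5, 6.0]
    ghg_kgco2e_per_kg: [2.0, 4.5]
    nutrients:
      protein: [0.0, 0.0]
      fiber: [0.0, 0.0]
      Ca: [0.0, 0.0]
      Fe: [0.0, 0.0]
      Mg: [0.0, 0.0]
      K: [0.0, 0.0]
      vitA: [0.0, 0.0]
      vitC: [0.0, 0.0]
      vitE: [0.14, 0.49]
      satfat: [0.08, 0.16]
      sugar_added: [0.0, 0.0]
      Na: [0.0, 0.0]
  tubers:
    energy_kcal_per_g: [0.7, 0.9]
    price_eur_per_kg: [0.6, 1.5]
    ghg_kgco2e_per_kg: [0.2, 0.6]
    nutrients:
      protein: [0.015, 0.025]
      fiber: [0.015, 0.025]
      Ca: [0.05, 0.15]
      Fe: [0.003, 0.008]
      Mg: [0.2, 0.25]
      K: [3.5, 4.5]
      vitA: [0.0, 0.0]
      vitC: [0.1, 0.2]
      vitE: [0.0, 0.001]
      satfat: [0.0, 0.0]
      sugar_added: [0.0, 0.0]
      Na: [0.02, 0.08]
  nuts:
    energy_kcal_per_g: [5.5, 6.5]
    price_eur_per_kg: [6.0, 15.0]
    ghg_kgco2e_per_kg: [1.5, 4.0]
    nutrients:
      protein: [0.14, 0.25]
      fiber: [0.07, 0.12]
      Ca: [0.5, 2.6]
      Fe: [0.02, 0.05]
      Mg: [1.5, 2.7]
      K: [5.5, 7.5]
      vitA: [0.0, 0.0]
      vitC: [0.0, 0.0]
      vitE: [0.05, 0.26]
      satfat: [0.04, 0.16]
      sugar_added: [0.0, 0.0]
      Na: [0.0, 0.05]
  white_meat:
    energy_kcal_per_g: [1.1, 1.9]
    price_eur_per_kg: [5.0, 9.0]
    ghg_kgco2e_per_kg: [4.0, 8.0]
    nutrients:
      protein: [0.18, 0.23]
      fiber: [0.0, 0.0]
      Ca: [0.05, 0.15]
      Fe: [0.007, 0.015]
      Mg: [0.2, 0.28]
      K: [2.5, 3.5]
      vitA: [0.05, 0.3]
      vitC: [0.0, 0.0]
      vitE: [0.002, 0.005]
      satfat: [0.01, 0.035]
      sugar_added: [0.0, 0.0]
      Na: [0.6, 0.9]
  eggs:
    energy_kcal_per_g: [1.4, 1.5]
    price_eur_per_kg: [2.5, 4.0]
    ghg_kgco2e_per_kg: [2.0, 4.0]
    nutrients:
      protein: [0.12, 0.13]
      fiber: [0.0, 0.0]
      Ca: [0.5, 0.6]
      Fe: [0.017, 0.022]
      Mg: [0.11, 0.13]
      K: [1.3, 1.5]
      vitA: [1.4, 1.9]
      vitC: [0.0, 0.0]
      vitE: [0.01, 0.013]
      satfat: [0.027, 0.033]
      sugar_added: [0.0, 0.0]
      Na: [1.2, 1.4]
  sweets:
    energy_kcal_per_g: [3.5, 5.5]
    price_eur_per_kg: [2.0, 8.0]
    ghg_kgco2e_per_kg: [1.5, 4.0]
    nutrients:
      protein: [0.02, 0.08]
      fiber: [0.0, 0.05]
      Ca: [0.1, 0.8]
      Fe: [0.005, 0.03]
      Mg: [0.2, 1.0]
      K: [1.0, 4.0]
      vitA: [0.0, 0.3]
      vitC: [0.0, 0.0]
      vitE: [0.01, 0.05]
      satfat: [0.05, 0.2]
      sugar_added: [0.3, 0.7]
      Na: [0.1, 3.0]
  beverages:
    energy_kcal_per_g: [0.2, 0.6]
    price_eur_per_kg: [0.5, 1.5]
    ghg_kgco2e_per_kg: [0.3, 1.0]
    nutrients:
      protein: [0.0, 0.035]
      fiber: [0.0, 0.01]
      Ca: [0.3, 1.2]
      Fe: [0.0, 0.003]
      Mg: [0.05, 0.15]
      K: [0.5, 1.8]
      vitA: [0.0, 0.1]
      vitC: [0.0, 0.1]
      vitE: [0.0, 0.005]
      satfat: [0.0, 0.003]
      sugar_added: [0.04, 0.11]
      Na: [0.05, 0.2]
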