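# Default rat (male Sprague-Dawley) system parameters for the minimal PBPK
# model. Values seeded from standard rodent physiology compendia (Brown et al.
# 1997; Davies & Morris 1993) and IVIVE scaling-factor surveys; the gut
# first-pass scaling pair (villous_blood_flow, gut_microsomal_protein_total)
# was calibrated once, globally, against a saturable intestinal first-pass
# dose series and then frozen for all compounds.
body_weight: 0.25            # kg
liver_weight: 9.15           # g (3.66% of body weight)
hepatic_blood_flow: 0.828    # L/h (13.8 ml/min)
villous_blood_flow: 0.50     # L/h, mucosal flow perfusing the enterocytes
mppgl: 40                    # mg microsomal protein / g liver
hpgl: 99                     # 10^6 hepatocytes / g liver
gut_microsomal_protein_total: 600  # mg microsomal protein, whole small intestine
intestine_radius: 0.18       # cm
small_intestine_transit_time: 1.5  # h
enterocyte_volume: 0.0015    # L
plasma_volume: 0.0078        # L (31.2 ml/kg)
hematocrit: 0.46
plasma_ph: 7.4
intracellular_ph: 7.0
blood_cell_ph: 7.22
dispersion_number: 0.17      # axial dispersion number for the dispersion liver model
permeability:
  # log10 Peff,human(cm/s) = c0 + c1 * PSA(A^2) + c2 * HBD
  psa_hbd: {c0: -2.546, c1: -0.011, c2: -0.278}
  # log10 Peff,human(1e-4 cm/s) = slope * log10 Papp(1e-6 cm/s) + intercept
  papp: {slope: 0.4926, intercept: -0.1454}
  # Peff,human = a * Peff,rat + b  (both in 1e-4 cm/s)
  interspecies: {a: 3.6, b: 0.03}
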