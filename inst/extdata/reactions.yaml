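# Reaction registry for the alkane-oxidizing / anammox consortium.
#
# Formation energies (gf_prime, kJ/mol) are standard transformed values at
# 298 K, pH 7, 1 M / 1 atm standard states, taken from the classical
# anaerobic-microbiology compilation of Thauer, Jungermann & Decker (1977,
# Bacteriol. Rev. 41:100-180; gas-phase alkanes from CRC Handbook). The
# pH-7 convention is carried entirely by the H+ entry (-39.87 = -RT ln 10^7).
# Reported reaction energies are table-dependent at the percent level.
compounds:
  C3H8:
    formula: {C: 3, H: 8}
    charge: 0
    phase: gas
    gf_prime: -23.4
  C4H10:
    formula: {C: 4, H: 10}
    charge: 0
    phase: gas
    gf_prime: -17.0
  CO2:
    formula: {C: 1, O: 2}
    charge: 0
    phase: gas
    gf_prime: -394.36
  N2:
    formula: {"N": 2}
    charge: 0
    phase: gas
    gf_prime: 0.0
  H2O:
    formula: {H: 2, O: 1}
    charge: 0
    phase: liquid
    gf_prime: -237.17
  NO3:
    formula: {"N": 1, O: 3}
    charge: -1
    phase: aqueous
    gf_prime: -111.34
  NO2:
    formula: {"N": 1, O: 2}
    charge: -1
    phase: aqueous
    gf_prime: -37.2
  NH4:
    formula: {"N": 1, H: 4}
    charge: 1
    phase: aqueous
    gf_prime: -79.37
  HCO3:
    formula: {C: 1, H: 1, O: 3}
    charge: -1
    phase: aqueous
    gf_prime: -586.85
  H:
    formula: {H: 1}
    charge: 1
    phase: aqueous
    gf_prime: -39.87
  biomass:
    # generic anammox biomass CH2O0.5N0.15; no reliable gf_prime, left unset
    formula: {C: 1, H: 2, O: 0.5, "N": 0.15}
    charge: 0
    phase: aqueous

reactions:
  # nitrate-dependent anaerobic propane oxidation to nitrite (n-DAPO, step 1)
  propane_nitrate_to_nitrite:
    stoich: {C3H8: -1, NO3: -10, CO2: 3, NO2: 10, H2O: 4}
    reference: C3H8
  # anammox with biomass synthesis (two-decimal literature stoichiometry)
  anammox:
    stoich: {NH4: -1, NO2: -1.32, HCO3: -0.066, H: -0.13,
             N2: 1.02, NO3: 0.26, H2O: 2.03, biomass: 0.066}
    reference: NH4
  # propane-driven denitrification of nitrite to dinitrogen gas
  propane_nitrite_to_n2:
    stoich: {C3H8: -3, NO2: -20, H: -20, CO2: 9, N2: 10, H2O: 22}
    reference: C3H8
  # butane analogues (13 NO3- per C4H10 by electron balance, 26 e-/mol)
  butane_nitrate_to_nitrite:
    stoich: {C4H10: -1, NO3: -13, CO2: 4, NO2: 13, H2O: 5}
    reference: C4H10
  butane_nitrite_to_n2:
    stoich: {C4H10: -3, NO2: -26, H: -26, CO2: 12, N2: 13, H2O: 28}
    reference: C4H10

# Registered redox conversions; electron counts are derived from mean
# oxidation states (O fixed at -II, H at +I, the named element balances
# the charge), not stored.
conversions:
  propane_to_co2:   {element: C, from: C3H8,  to: CO2}
  butane_to_co2:    {element: C, from: C4H10, to: CO2}
  ammonium_to_n2:   {element: "N", from: NH4,   to: N2}
  nitrate_to_n2:    {element: "N", from: NO3,   to: N2}
  nitrate_to_nitrite: {element: "N", from: NO3, to: NO2}
  nitrite_to_n2:    {element: "N", from: NO2,   to: N2}
  nitrite_to_ammonium: {element: "N", from: NO2, to: NH4}
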