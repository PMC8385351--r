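# Boundary-condition presets for the E. coli core subnetwork fixtures.
glycolysis_ppp:
  base_chemostats: [ADP, ATP, CO2, G6P, H, H2O, NAD, NADH, NADP, NADPH, PI, PYR]
  configs:
    r5p_nadph:            # pathway i: R5P and NADPH generation
      extra_chemostats: [R5P]
      flowstats: [PGI, TKT2]
    r5p:                  # pathway ii: R5P generation
      extra_chemostats: [R5P]
      flowstats: [GAPD, G6PDH2R]
    nadph:                # pathway iii: NADPH generation
      extra_chemostats: []
      flowstats: [GAPD]
  estimation_chemostats: [ADP, ATP, CO2, G3P, G6P, H, H2O, NADP, NADPH, R5P]
tca:
  chemostats: [PYR, CO2, ADP, ATP, H2O, NAD, NADH, PI, NADP, NADPH, H, Q8, Q8H2, FOR]
respiration:
  chemostats: [GLCDE, CO2, O2, ADP, ATP, H2O, PI, H]
  common_species: [PYR, ATP, ADP, PI, H, H2O, NAD, NADH, NADP, NADPH, HE, Q8, Q8H2]
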