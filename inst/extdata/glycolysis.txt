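# Glycolysis module (E. coli core subnetwork)
GLCPTS: GLCDE + PEP <-> G6P + PYR
PGI: G6P <-> F6P
PFK: ATP + F6P <-> ADP + FDP + H
FBP: FDP + H2O <-> F6P + PI
FBA: FDP <-> DHAP + G3P
TPI: DHAP <-> G3P
GAPD: G3P + NAD + PI <-> 13DPG + H + NADH
PGK: 3PG + ATP <-> 13DPG + ADP
PGM: 2PG <-> 3PG
ENO: 2PG <-> H2O + PEP
PYK: ADP + H + PEP <-> ATP + PYR
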