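# Upper glycolysis + pentose phosphate pathway (E. coli core subnetwork)
PGI: G6P <-> F6P
PFK: ATP + F6P <-> ADP + FDP + H
FBA: FDP <-> DHAP + G3P
TPI: DHAP <-> G3P
GAPD: G3P + NAD + PI <-> 13DPG + H + NADH
G6PDH2R: G6P + NADP <-> 6PGL + H + NADPH
PGL: 6PGL + H2O <-> 6PGC + H
GND: 6PGC + NADP <-> CO2 + NADPH + RU5P
RPI: RU5P <-> R5P
TKT1: R5P + XU5P <-> G3P + S7P
TKT2: E4P + XU5P <-> F6P + G3P
TALA: G3P + S7P <-> E4P + F6P
RPE: RU5P <-> XU5P
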