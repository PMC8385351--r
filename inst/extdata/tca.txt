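# TCA cycle module, including pyruvate dehydrogenase and pyruvate formate
# lyase (E. coli core subnetwork)
CS: ACCOA + H2O + OAA <-> CIT + COA + H
ACONTA: CIT <-> ACON + H2O
ACONTB: ACON + H2O <-> ICIT
ICDHYR: ICIT + NADP <-> AKG + CO2 + NADPH
AKGDH: AKG + COA + NAD <-> CO2 + NADH + SUCCOA
SUCOAS: ADP + PI + SUCCOA <-> ATP + COA + SUCC
SUCDI: Q8 + SUCC <-> FUM + Q8H2
FRD7: FUM + Q8H2 <-> Q8 + SUCC
FUM: FUM + H2O <-> MAL
MDH: MAL + NAD <-> H + NADH + OAA
PDH: COA + NAD + PYR <-> ACCOA + CO2 + NADH
PFL: COA + PYR <-> ACCOA + FOR
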