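# Electron transport chain (cytochrome oxidase doubled to integer O2)
NADH16: 4 H + NADH + Q8 <-> 3 HE + NAD + Q8H2
CYTBD: 4 H + O2 + 2 Q8H2 <-> 2 H2O + 4 HE + 2 Q8
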