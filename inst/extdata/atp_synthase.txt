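# ATP synthase
ATPS4R: ADP + 4 HE + PI <-> ATP + H2O + 3 H
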