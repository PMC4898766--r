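path,species_morpho,species_bptp
AH,31,32
DD,22,23
MN,57,59
NO,48,52
ST,58,61
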