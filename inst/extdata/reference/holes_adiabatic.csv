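nucleotide,component,mean,se
dAMP,dRT,0.84,0.02
dAMP,BASE,0.71,0.02
dAMP,RIBOSE,0.13,0.03
dAMP,PHOSPHATE,-0.00,0.02
dGMP,dRT,0.86,0.03
dGMP,BASE,0.77,0.03
dGMP,RIBOSE,0.06,0.03
dGMP,PHOSPHATE,0.04,0.02
dCMP,dRT,0.85,0.03
dCMP,BASE,0.76,0.04
dCMP,RIBOSE,0.05,0.04
dCMP,PHOSPHATE,0.04,0.02
dTMP,dRT,0.86,0.02
dTMP,BASE,0.80,0.04
dTMP,RIBOSE,0.04,0.03
dTMP,PHOSPHATE,0.01,0.02
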