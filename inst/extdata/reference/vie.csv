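nucleotide,framework,mean,se
dAMP,qmm,7.26,0.08
dAMP,gas,5.68,0.04
dGMP,qmm,6.92,0.07
dGMP,gas,5.51,0.04
dCMP,qmm,7.45,0.07
dCMP,gas,5.69,0.04
dTMP,qmm,7.63,0.06
dTMP,gas,5.95,0.04
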