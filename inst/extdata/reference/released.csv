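nucleotide,framework,mean,se
dAMP,qmm,1.86,0.11
dAMP,pol,1.48,0.10
dAMP,gas,0.17,0.04
dGMP,qmm,1.97,0.15
dGMP,pol,1.42,0.10
dGMP,gas,0.33,0.04
dCMP,qmm,1.62,0.08
dCMP,pol,1.20,0.08
dCMP,gas,0.09,0.04
dTMP,qmm,1.76,0.09
dTMP,pol,1.29,0.09
dTMP,gas,0.12,0.05
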