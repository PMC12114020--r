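nucleotide,framework,mean,se
dAMP,qmm,5.40,0.08
dAMP,pol,5.78,0.09
dAMP,gas,5.51,0.06
dGMP,qmm,4.94,0.11
dGMP,pol,5.50,0.09
dGMP,gas,5.18,0.05
dCMP,qmm,5.84,0.06
dCMP,pol,6.25,0.07
dCMP,gas,5.60,0.05
dTMP,qmm,5.86,0.07
dTMP,pol,6.33,0.09
dTMP,gas,5.82,0.05
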