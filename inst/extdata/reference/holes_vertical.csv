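nucleotide,embedding,component,mean,se
dAMP,qmm,dRT,0.73,0.01
dAMP,qmm,BASE,0.62,0.01
dAMP,qmm,RIBOSE,0.08,0.01
dAMP,qmm,PHOSPHATE,0.03,0.01
dAMP,gas,dRT,0.32,0.02
dAMP,gas,BASE,0.29,0.02
dAMP,gas,RIBOSE,0.03,0.01
dAMP,gas,PHOSPHATE,0.01,0.01
dGMP,qmm,dRT,0.75,0.01
dGMP,qmm,BASE,0.66,0.01
dGMP,qmm,RIBOSE,0.05,0.01
dGMP,qmm,PHOSPHATE,0.03,0.01
dGMP,gas,dRT,0.40,0.02
dGMP,gas,BASE,0.37,0.02
dGMP,gas,RIBOSE,0.02,0.01
dGMP,gas,PHOSPHATE,0.02,0.01
dCMP,qmm,dRT,0.76,0.01
dCMP,qmm,BASE,0.61,0.01
dCMP,qmm,RIBOSE,0.07,0.01
dCMP,qmm,PHOSPHATE,0.09,0.01
dCMP,gas,dRT,0.24,0.02
dCMP,gas,BASE,0.20,0.03
dCMP,gas,RIBOSE,0.04,0.01
dCMP,gas,PHOSPHATE,-0.01,0.01
dTMP,qmm,dRT,0.75,0.01
dTMP,qmm,BASE,0.58,0.01
dTMP,qmm,RIBOSE,0.05,0.01
dTMP,qmm,PHOSPHATE,0.11,0.01
dTMP,gas,dRT,0.25,0.02
dTMP,gas,BASE,0.21,0.02
dTMP,gas,RIBOSE,0.02,0.01
dTMP,gas,PHOSPHATE,0.02,0.01
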