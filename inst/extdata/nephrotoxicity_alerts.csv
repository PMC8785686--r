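bit_id,smarts
KR413,[!#1][CH2][CH2]c1[cH][cH][cH][cH][cH]1
KR848,[!#1][NH]C(=O)[CH]([CH3])[NH]C(=O)[!#1]
KR1798,[!#1]c1[cH][cH]c(F)[cH][cH]1
KR2444,[!#1]N1[CH2][CH2]N([CH3])[CH2][CH2]1
KR3206,c1nc2ccccc2[nH]1
KR3280,CC(=O)c1ccc(N)cc1
KR3540,Cc1ccc(cc1)c2ccccc2
KR3548,Cc1ccc(F)cc1
KR3586,Cc1cccc(F)c1
KR4029,CS(c1nc2ccccc2[nH]1)
KR4064,Fc1cccc(C=O)c1
KR4065,Fc1cccc(F)c1
KR4081,N#Cc1ccccc1
KR4252,Nc1ccc(F)cc1
KR4556,O=CNCCCCNC=O
KR4651,OC(=O)C1CCCN1
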