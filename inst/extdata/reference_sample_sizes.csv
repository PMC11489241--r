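cohort,group,power,slowing,n_fsara,n_composite
CRC-SCA,all,0.80,0.3,750,256
CRC-SCA,all,0.80,0.5,271,93
CRC-SCA,all,0.90,0.3,1004,342
CRC-SCA,all,0.90,0.5,362,124
CRC-SCA,SCA3,0.80,0.3,561,209
CRC-SCA,SCA3,0.80,0.5,203,76
CRC-SCA,SCA3,0.90,0.3,751,279
CRC-SCA,SCA3,0.90,0.5,271,101
EUROSCA,all,0.80,0.3,668,140
EUROSCA,all,0.80,0.5,241,51
EUROSCA,all,0.90,0.3,893,187
EUROSCA,all,0.90,0.5,323,68
EUROSCA,SCA3,0.80,0.3,504,142
EUROSCA,SCA3,0.80,0.5,182,52
EUROSCA,SCA3,0.90,0.3,674,189
EUROSCA,SCA3,0.90,0.5,244,69
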