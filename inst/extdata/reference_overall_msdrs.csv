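cohort,group,endpoint,msdr
CRC-SCA,all,composite,0.8276
CRC-SCA,all,fsara,0.4826
EUROSCA,all,composite,1.1206
EUROSCA,all,fsara,0.5117
CRC-SCA,SCA3,composite,0.9171
CRC-SCA,SCA3,fsara,0.5582
EUROSCA,SCA3,composite,1.1157
EUROSCA,SCA3,fsara,0.5893
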