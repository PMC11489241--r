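cohort,group,item_id,msdr,vip,weight,pct_contribution
CRC-SCA,all,fsara_gait,0.3975,0.8044,5.0057,14.83
CRC-SCA,all,fars_func,0.3902,0.5540,8.7293,25.86
CRC-SCA,all,fsara_stance,0.2481,1.0414,4.7659,14.12
CRC-SCA,all,fsara_speech,0.2835,0.6300,3.8264,11.34
CRC-SCA,all,fsara_sitting,0.1836,0.4652,0.0000,NA
CRC-SCA,all,cgi,0.7713,1.8298,11.4228,33.85
EUROSCA,all,fsara_gait,0.3244,0.7828,6.1773,12.26
EUROSCA,all,fsara_stance,0.3791,0.8956,8.3214,16.51
EUROSCA,all,fsara_speech,0.2846,0.6321,5.2110,10.34
EUROSCA,all,fsara_sitting,0.2587,0.6122,3.9369,7.81
EUROSCA,all,cgi,1.1121,1.6765,26.7503,53.08
CRC-SCA,SCA3,fsara_gait,0.4604,0.6417,4.5390,10.45
CRC-SCA,SCA3,fars_func,0.1688,0.4741,10.8056,24.87
CRC-SCA,SCA3,fsara_stance,0.2683,1.0522,9.9743,22.95
CRC-SCA,SCA3,fsara_speech,0.2614,0.4952,4.2284,9.73
CRC-SCA,SCA3,fsara_sitting,0.2538,NA,0.0000,NA
CRC-SCA,SCA3,cgi,0.9125,1.7353,13.9060,32.00
EUROSCA,SCA3,fsara_gait,0.2952,0.6718,2.5315,4.83
EUROSCA,SCA3,fsara_stance,0.5629,1.0763,13.5141,25.76
EUROSCA,SCA3,fsara_speech,0.2320,0.6486,10.7757,20.54
EUROSCA,SCA3,fsara_sitting,0.3056,0.5132,2.0793,3.96
EUROSCA,SCA3,cgi,1.0742,1.6450,23.5624,44.91
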