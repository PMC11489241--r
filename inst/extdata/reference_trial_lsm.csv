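model_cohort,model_group,quantity,lsm,se,p_value
CRC-SCA,all,placebo,3.6254,0.6573,NA
CRC-SCA,all,treated,0.9001,0.6847,NA
CRC-SCA,all,difference,2.7254,0.9496,0.0046
EUROSCA,all,placebo,6.8458,1.4025,NA
EUROSCA,all,treated,1.2550,1.4611,NA
EUROSCA,all,difference,5.5908,2.0274,0.0064
CRC-SCA,SCA3,placebo,4.4884,0.8262,NA
CRC-SCA,SCA3,treated,0.8833,0.8605,NA
CRC-SCA,SCA3,difference,3.6051,1.1944,0.0030
EUROSCA,SCA3,placebo,6.3255,1.3113,NA
EUROSCA,SCA3,treated,0.8086,1.3648,NA
EUROSCA,SCA3,difference,5.5169,1.8954,0.0041
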