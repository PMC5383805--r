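group,advocacy,n,before_pct
gun_type,gun_rights,40069,28.29
gun_type,gun_control,18929,14.97
gun_type,total,58998,24.01
shooting,gun_rights,2490,39.04
shooting,gun_control,455,17.58
shooting,total,2945,35.72
ammunition,gun_rights,2316,36.44
ammunition,gun_control,170,20.59
ammunition,total,2486,35.36
law_related,gun_rights,973,21.69
law_related,gun_control,1179,11.62
law_related,total,2152,16.17
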