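group,class_label,before_n,after_n,is_total
gun_type,"retail content, .com",370002,595793,FALSE
gun_type,"news content, .com",340883,254806,FALSE
gun_type,"educational content, .com",196435,363860,FALSE
gun_type,"educational content, .org",46886,138093,FALSE
gun_type,"other content, .com",293009,481025,FALSE
gun_type,total,1345833,2019526,TRUE
shooting,"news content, .com",51678,596555,FALSE
shooting,"educational content, .com",26941,67209,FALSE
shooting,"educational content, .org",7911,46919,FALSE
shooting,"showbiz content, .com",15732,28403,FALSE
shooting,"other content, .com",98564,221328,FALSE
shooting,total,236050,1023767,TRUE
ammunition,"retail content, .com",163272,445974,FALSE
ammunition,"educational content, .com",31256,64431,FALSE
ammunition,"news content, .com",10849,50176,FALSE
ammunition,"other content, .com",36104,64607,FALSE
ammunition,total,268670,685488,TRUE
law_related,"educational content, .org",2817,22612,FALSE
law_related,"educational content, .com",1823,10650,FALSE
law_related,"educational content, .edu",431,2991,FALSE
law_related,"news content, .com",383,2280,FALSE
law_related,"other content, .com",1502,7476,FALSE
law_related,total,7965,50615,TRUE
control,"retail content, .com",75551,66658,FALSE
control,"educational content, .com",45550,42414,FALSE
control,"other content, .com",137068,129152,FALSE
control,"other content, .other",12254,11351,FALSE
control,"other content, .org",10233,9724,FALSE
control,total,308603,281927,TRUE
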