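table,level,n,total_n
search_keywords,gun_type,3370523,5653588
search_keywords,shooting,1270122,5653588
search_keywords,ammunition,954363,5653588
search_keywords,law_related,58580,5653588
search_keywords,control,597859,597859
tld,commercial,4976990,5653588
tld,noncommercial,374863,5653588
tld,government,59939,5653588
tld,educational_institution,9419,5653588
tld,other,232377,5653588
content,retail,1714504,5653588
content,news,1321706,5653588
content,educational,1148897,5653588
content,showbiz,118174,5653588
content,other,1350307,5653588
advocacy,gun_rights,45848,66581
advocacy,gun_control,20733,66581
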