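jurisdiction,abbrev,stratum,population,basis
Ontario,ON,total,14223942,census
Quebec,PQ,total,8501833,census
British Columbia,BC,total,5000879,census
Alberta,AB,total,4262635,census
Manitoba,MB,total,1342153,census
Saskatchewan,SK,total,1132505,census
Nova Scotia,NS,total,969383,census
New Brunswick,NB,total,775610,census
Newfoundland and Labrador,NL,total,510550,census
Prince Edward Island,PE,total,154331,census
Yukon,YT,total,40232,census
Northwest Territories,NT,total,41070,census
Nunavut,NU,total,36858,census
Canada,CA,total,36991981,census
Ontario,ON,18-39,4517570,census
Quebec,PQ,18-39,2337880,census
British Columbia,BC,18-39,1568044,census
Alberta,AB,18-39,1395268,census
Manitoba,MB,18-39,429186,census
Saskatchewan,SK,18-39,351071,census
Nova Scotia,NS,18-39,273295,census
New Brunswick,NB,18-39,199309,census
Newfoundland and Labrador,NL,18-39,126163,census
Prince Edward Island,PE,18-39,47631,census
Yukon,YT,18-39,14376,synthetic
Northwest Territories,NT,18-39,14676,synthetic
Nunavut,NU,18-39,13171,synthetic
Canada,CA,18-39,11287640,census
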