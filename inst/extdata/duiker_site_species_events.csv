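site,C. callipygus,C. castaneus,C. leucogaster,C. nigrifrons,C. silvicultor,P. congica
Dja CMR,70,30,0,1,60,417
Makalaya CMR,140,30,1,1,32,151
Mindourou 1 CMR,7,13,0,0,6,42
Mindourou 2 CMR,27,17,0,1,14,99
Mindourou 3 CMR,12,13,0,0,4,86
Ingolo COG,1,35,0,0,10,113
Ngombe COG,230,148,1,0,55,545
Bambidie GBN,100,45,12,1,14,52
Djoutou GBN,102,31,19,3,19,359
Ndambie GBN,116,67,25,0,30,77
Ovan GBN,140,36,3,8,35,601
Maduda RDC,0,4,0,27,0,20
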