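level,code,name,parent_code
1,EUR,Europe,
1,AFR,Africa,
1,TEA,Asia-Temperate,
1,TRA,Asia-Tropical,
1,AUS,Australasia,
1,PAC,Pacific,
1,NAM,North America,
1,SAM,South America,
1,ANT,Antarctic,
2,NEU,Northern Europe,EUR
2,SEU,Southwestern Europe,EUR
2,NAF,Northern Africa,AFR
2,WTA,Western Tropical Africa,AFR
2,MDG,Madagascar,AFR
2,RUF,Russian Far East,TEA
2,CHN,China,TEA
2,EAS,Eastern Asia,TEA
2,IND,Indian Subcontinent,TRA
2,MLY,Malesia,TRA
2,AUT,Australia,AUS
2,NZL,New Zealand,AUS
2,ECA,Eastern Canada,NAM
2,WCA,Western Canada,NAM
2,USN,Northeastern U.S.A.,NAM
2,MXC,Mexico,NAM
2,BRA,Brazil,SAM
2,SSA,Southern South America,SAM
3,ONT,Ontario,ECA
3,QUE,Quebec,ECA
3,CHC,China South-Central,CHN
3,CHS,China Southeast,CHN
3,NSW,New South Wales,AUT
3,BZL,Brazil Southeast,BRA
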