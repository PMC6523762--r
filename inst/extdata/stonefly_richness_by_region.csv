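family,suborder,infraorder,global,EUR,AFR,TEA,TRA,AUS,NAM,SAM
Diamphipnoidae,Antarctoperlaria,,6,0,0,0,0,0,0,6
Eustheniidae,Antarctoperlaria,,22,0,0,0,0,20,0,2
Austroperlidae,Antarctoperlaria,,15,0,0,0,0,11,0,4
Gripopterygidae,Antarctoperlaria,,313,0,0,0,0,214,0,99
Capniidae,Arctoperlaria,Euholognatha,295,28,4,104,9,0,167,0
Leuctridae,Arctoperlaria,Euholognatha,384,144,9,148,28,0,64,0
Nemouridae,Arctoperlaria,Euholognatha,694,150,13,338,148,0,80,0
Notonemouridae,Arctoperlaria,Euholognatha,120,0,39,0,0,62,0,20
Taeniopterygidae,Arctoperlaria,Euholognatha,104,48,2,27,1,0,36,0
Scopuridae,Arctoperlaria,Euholognatha,8,0,0,8,0,0,0,0
Chloroperlidae,Arctoperlaria,Systellognatha,204,23,1,71,6,0,107,0
Perlidae,Arctoperlaria,Systellognatha,1120,20,10,330,276,0,125,397
Perlodidae,Arctoperlaria,Systellognatha,340,76,2,118,6,0,152,0
Peltoperlidae,Arctoperlaria,Systellognatha,71,0,0,24,23,0,24,0
Pteronarcyidae,Arctoperlaria,Systellognatha,12,0,0,2,0,0,10,0
Styloperlidae,Arctoperlaria,Systellognatha,10,0,0,9,1,0,0,0
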