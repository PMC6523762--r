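area,code,type,n_described
Global,GLOBAL,global,1657
Asia-Temperate,TEA,region,519
South America,SAM,region,343
China,China,country,335
Asia-Tropical,TRA,region,278
North America,NAM,region,250
Australasia,AUS,region,173
Europe,EUR,region,119
Africa,AFR,region,17
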