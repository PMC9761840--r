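species,chemical,lc50_mg_per_L,lower95,upper95
catfish,atrazine,17.463,15.486,19.201
catfish,chlorpyrifos,0.515,0.349,0.786
catfish,mancozeb,24.383,16.360,31.253
catfish,lambda-cyhalothrin,0.000434,0.000384,0.000482
tilapia,atrazine,10.926,8.850,13.409
tilapia,chlorpyrifos,0.111,0.103,0.121
tilapia,mancozeb,3.028,2.665,3.424
tilapia,lambda-cyhalothrin,0.008412,0.007015,0.010062
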