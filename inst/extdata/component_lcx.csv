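species,chemical,percent,lcx_mg_per_L
catfish,atrazine,5,7.025
catfish,atrazine,15,10.894
catfish,atrazine,35,15.033
catfish,atrazine,60,19.094
catfish,atrazine,90,25.631
catfish,mancozeb,5,5.363
catfish,mancozeb,15,12.398
catfish,mancozeb,35,19.928
catfish,mancozeb,60,27.313
catfish,mancozeb,90,39.203
catfish,chlorpyrifos,5,0.125
catfish,chlorpyrifos,15,0.270
catfish,chlorpyrifos,35,0.424
catfish,chlorpyrifos,60,0.575
catfish,chlorpyrifos,90,0.819
catfish,lambda-cyhalothrin,5,0.000186
catfish,lambda-cyhalothrin,15,0.000278
catfish,lambda-cyhalothrin,35,0.000376
catfish,lambda-cyhalothrin,60,0.000473
catfish,lambda-cyhalothrin,90,0.000628
tilapia,atrazine,5,3.95
tilapia,atrazine,15,5.76
tilapia,atrazine,35,8.61
tilapia,atrazine,60,12.78
tilapia,atrazine,90,24.14
tilapia,mancozeb,5,1.87
tilapia,mancozeb,15,2.23
tilapia,mancozeb,35,2.70
tilapia,mancozeb,60,3.26
tilapia,mancozeb,90,4.42
tilapia,chlorpyrifos,5,0.08
tilapia,chlorpyrifos,15,0.09
tilapia,chlorpyrifos,35,0.10
tilapia,chlorpyrifos,60,0.12
tilapia,chlorpyrifos,90,0.15
tilapia,lambda-cyhalothrin,5,0.003
tilapia,lambda-cyhalothrin,15,0.004
tilapia,lambda-cyhalothrin,35,0.007
tilapia,lambda-cyhalothrin,60,0.010
tilapia,lambda-cyhalothrin,90,0.020
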