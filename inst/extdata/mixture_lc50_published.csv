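species,mixture,model,lc50_mg_per_L,lower95,upper95,mdr_printed
catfish,atrazine-mancozeb,observed,11.1,10.6,11.6,NA
catfish,atrazine-mancozeb,hm,14.3,12.3,16.3,1.28
catfish,atrazine-mancozeb,ca,18.5,15.8,21.9,1.67
catfish,atrazine-chlorpyrifos,observed,9.2,8.6,9.8,NA
catfish,atrazine-chlorpyrifos,hm,8.5,7.1,9.9,0.92
catfish,atrazine-chlorpyrifos,ca,8.3,7.1,9.9,0.90
catfish,atrazine-lambda-cyhalothrin,observed,22.1,20.1,38.5,NA
catfish,atrazine-lambda-cyhalothrin,hm,8.7,7.3,10.1,0.39
catfish,atrazine-lambda-cyhalothrin,ca,8.3,7.3,9.6,0.38
catfish,mancozeb-chlorpyrifos,observed,5.3,4.9,5.8,NA
catfish,mancozeb-chlorpyrifos,hm,9.7,8.4,11.7,1.83
catfish,mancozeb-chlorpyrifos,ca,11.3,9.4,13.9,2.13
catfish,mancozeb-lambda-cyhalothrin,observed,7.5,6.6,8.5,NA
catfish,mancozeb-lambda-cyhalothrin,hm,9.5,7.8,11.2,1.27
catfish,mancozeb-lambda-cyhalothrin,ca,11.3,9.6,13.5,1.51
catfish,lambda-cyhalothrin-chlorpyrifos,observed,0.27,0.22,0.31,NA
catfish,lambda-cyhalothrin-chlorpyrifos,hm,0.55,0.467,0.640,2.04
catfish,lambda-cyhalothrin-chlorpyrifos,ca,0.24,0.21,0.28,0.89
catfish,quaternary,observed,4.6,3.8,5.5,NA
catfish,quaternary,hm,14.9,12.9,17.1,3.24
catfish,quaternary,ca,9.8,8.4,11.7,2.13
tilapia,atrazine-mancozeb,observed,6.7,2.4,9.7,NA
tilapia,atrazine-mancozeb,hm,5.9,4.5,7.1,0.88
tilapia,atrazine-mancozeb,ca,6.9,5.9,8.1,1.03
tilapia,atrazine-chlorpyrifos,observed,2.6,1.8,3.1,NA
tilapia,atrazine-chlorpyrifos,hm,4.8,3.7,5.7,1.85
tilapia,atrazine-chlorpyrifos,ca,5.6,5.1,6.4,2.15
tilapia,atrazine-lambda-cyhalothrin,observed,9.3,6.5,11.1,NA
tilapia,atrazine-lambda-cyhalothrin,hm,4.51,3.5,5.4,0.49
tilapia,atrazine-lambda-cyhalothrin,ca,5.3,4.4,6.6,0.57
tilapia,mancozeb-chlorpyrifos,observed,1.2,1.1,1.3,NA
tilapia,mancozeb-chlorpyrifos,hm,2.5,2.3,2.8,2.08
tilapia,mancozeb-chlorpyrifos,ca,1.487,NA,NA,1.24
tilapia,mancozeb-lambda-cyhalothrin,observed,5.7,4.9,6.5,NA
tilapia,mancozeb-lambda-cyhalothrin,hm,2.4,2.1,2.7,0.42
tilapia,mancozeb-lambda-cyhalothrin,ca,1.6,1.0,5.0,0.28
tilapia,lambda-cyhalothrin-chlorpyrifos,observed,0.15,0.13,0.17,NA
tilapia,lambda-cyhalothrin-chlorpyrifos,hm,0.16,0.15,0.18,1.07
tilapia,lambda-cyhalothrin-chlorpyrifos,ca,0.06,0.05,0.07,0.40
tilapia,quaternary,observed,1.09,1.01,1.17,NA
tilapia,quaternary,hm,6.0,4.8,7.0,5.50
tilapia,quaternary,ca,3.4,3.0,4.0,3.12
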