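species,chemical,concentration_mg_per_L,lt50_h
catfish,atrazine,13,148.82
catfish,atrazine,16,149.70
catfish,atrazine,19,103.85
catfish,atrazine,21,53.55
catfish,atrazine,24,16.79
catfish,chlorpyrifos,0.25,538.44
catfish,chlorpyrifos,0.40,209.83
catfish,chlorpyrifos,0.55,49.59
catfish,chlorpyrifos,0.70,29.85
catfish,chlorpyrifos,1.00,8.28
catfish,mancozeb,8,1115.47
catfish,mancozeb,20,226.26
catfish,mancozeb,32,80.56
catfish,mancozeb,38,39.66
catfish,mancozeb,42,13.01
catfish,lambda-cyhalothrin,0.00025,214.82
catfish,lambda-cyhalothrin,0.00038,103.90
catfish,lambda-cyhalothrin,0.00050,37.17
catfish,lambda-cyhalothrin,0.00063,10.40
catfish,lambda-cyhalothrin,0.00075,3.24
tilapia,chlorpyrifos,0.08,646.81
tilapia,chlorpyrifos,0.10,245.68
tilapia,chlorpyrifos,0.13,22.02
tilapia,chlorpyrifos,0.17,10.19
tilapia,mancozeb,1.4,2769.46
tilapia,mancozeb,2.2,500.02
tilapia,mancozeb,3.2,58.07
tilapia,mancozeb,4.8,13.56
tilapia,lambda-cyhalothrin,0.0025,317.13
tilapia,lambda-cyhalothrin,0.0050,221.85
tilapia,lambda-cyhalothrin,0.0075,110.75
tilapia,lambda-cyhalothrin,0.0100,42.61
tilapia,lambda-cyhalothrin,0.0125,28.52
tilapia,lambda-cyhalothrin,0.0150,15.20
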