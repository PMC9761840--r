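species,mixture,component_index,chemical,ratio_weight,ratio_source,stock_g_per_L
catfish,atrazine-mancozeb,1,atrazine,1.39,printed_order_corrected,2.39
catfish,atrazine-mancozeb,2,mancozeb,1,printed_order_corrected,2.39
catfish,atrazine-chlorpyrifos,1,atrazine,33.95,printed,3.495
catfish,atrazine-chlorpyrifos,2,chlorpyrifos,1,printed,3.495
catfish,mancozeb-chlorpyrifos,1,mancozeb,47.35,printed,4.84
catfish,mancozeb-chlorpyrifos,2,chlorpyrifos,1,printed,4.84
catfish,atrazine-lambda-cyhalothrin,1,atrazine,40.28,printed,4.0301
catfish,atrazine-lambda-cyhalothrin,2,lambda-cyhalothrin,0.001,printed,4.0301
catfish,mancozeb-lambda-cyhalothrin,1,mancozeb,56.18,printed,5.6201
catfish,mancozeb-lambda-cyhalothrin,2,lambda-cyhalothrin,0.001,printed,5.6201
catfish,lambda-cyhalothrin-chlorpyrifos,1,lambda-cyhalothrin,0.001,printed,0.1188
catfish,lambda-cyhalothrin-chlorpyrifos,2,chlorpyrifos,1.18,printed,0.1188
catfish,quaternary,1,atrazine,17.463,equitoxic_lc50,9.7651
catfish,quaternary,2,mancozeb,24.383,equitoxic_lc50,9.7651
catfish,quaternary,3,chlorpyrifos,0.515,equitoxic_lc50,9.7651
catfish,quaternary,4,lambda-cyhalothrin,0.000434,equitoxic_lc50,9.7651
tilapia,atrazine-mancozeb,1,atrazine,3.61,printed,4.61
tilapia,atrazine-mancozeb,2,mancozeb,1,printed,4.61
tilapia,atrazine-chlorpyrifos,1,atrazine,98.47,printed,9.84
tilapia,atrazine-chlorpyrifos,2,chlorpyrifos,1,printed,9.84
tilapia,mancozeb-chlorpyrifos,1,mancozeb,27.3,printed,2.83
tilapia,mancozeb-chlorpyrifos,2,chlorpyrifos,1,printed,2.83
tilapia,atrazine-lambda-cyhalothrin,1,atrazine,12.99,printed,13
tilapia,atrazine-lambda-cyhalothrin,2,lambda-cyhalothrin,0.01,printed,13
tilapia,mancozeb-lambda-cyhalothrin,1,mancozeb,3.60,printed,3.61
tilapia,mancozeb-lambda-cyhalothrin,2,lambda-cyhalothrin,0.01,printed,3.61
tilapia,lambda-cyhalothrin-chlorpyrifos,1,lambda-cyhalothrin,1,printed,0.355
tilapia,lambda-cyhalothrin-chlorpyrifos,2,chlorpyrifos,13.21,printed,0.355
tilapia,quaternary,1,atrazine,1.299,printed,16.732
tilapia,quaternary,2,mancozeb,0.360,printed,16.732
tilapia,quaternary,3,chlorpyrifos,0.0132,printed,16.732
tilapia,quaternary,4,lambda-cyhalothrin,0.001,printed,16.732
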