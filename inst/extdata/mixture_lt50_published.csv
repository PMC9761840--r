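species,mixture,total_mg_per_L,lt50_mix_h,consistent
catfish,atrazine-mancozeb,5,6973.90,TRUE
catfish,atrazine-mancozeb,10,425.35,TRUE
catfish,atrazine-mancozeb,15,79.42,TRUE
catfish,atrazine-mancozeb,20,23.85,TRUE
catfish,atrazine-mancozeb,25,9.37,FALSE
catfish,atrazine-chlorpyrifos,4,3181.6,TRUE
catfish,atrazine-chlorpyrifos,8,156.62,TRUE
catfish,atrazine-chlorpyrifos,12,26.88,TRUE
catfish,atrazine-chlorpyrifos,16,7.70,TRUE
catfish,atrazine-chlorpyrifos,20,2.92,TRUE
catfish,atrazine-lambda-cyhalothrin,3.5,5289.83,TRUE
catfish,atrazine-lambda-cyhalothrin,7.5,190.97,TRUE
catfish,atrazine-lambda-cyhalothrin,11.5,29.65,TRUE
catfish,atrazine-lambda-cyhalothrin,15.5,8.07,TRUE
catfish,atrazine-lambda-cyhalothrin,19.5,2.97,TRUE
catfish,mancozeb-chlorpyrifos,1.5,55090.41,FALSE
catfish,mancozeb-chlorpyrifos,4.5,1319.15,FALSE
catfish,mancozeb-chlorpyrifos,7.5,232.63,FALSE
catfish,mancozeb-chlorpyrifos,10.5,74.18,TRUE
catfish,mancozeb-chlorpyrifos,15.5,19.76,TRUE
catfish,mancozeb-lambda-cyhalothrin,4,1872.10,TRUE
catfish,mancozeb-lambda-cyhalothrin,8,177.72,TRUE
catfish,mancozeb-lambda-cyhalothrin,12,44.83,TRUE
catfish,mancozeb-lambda-cyhalothrin,16,16.87,TRUE
catfish,mancozeb-lambda-cyhalothrin,20,7.91,TRUE
catfish,lambda-cyhalothrin-chlorpyrifos,0.05,1800890.66,TRUE
catfish,lambda-cyhalothrin-chlorpyrifos,0.25,2579.26,TRUE
catfish,lambda-cyhalothrin-chlorpyrifos,0.45,235.93,TRUE
catfish,lambda-cyhalothrin-chlorpyrifos,0.65,52.84,TRUE
catfish,lambda-cyhalothrin-chlorpyrifos,0.85,17.74,TRUE
catfish,quaternary,8,985.14,TRUE
catfish,quaternary,12,231.97,TRUE
catfish,quaternary,16,81.94,TRUE
catfish,quaternary,20,36.20,TRUE
catfish,quaternary,24,18.44,TRUE
tilapia,atrazine-mancozeb,1.5,4676.83,TRUE
tilapia,atrazine-mancozeb,3.9,153.00,FALSE
tilapia,atrazine-mancozeb,8.5,32.39,TRUE
tilapia,atrazine-mancozeb,12,11.11,TRUE
tilapia,atrazine-mancozeb,15.5,4.70,TRUE
tilapia,atrazine-chlorpyrifos,3,340.30,TRUE
tilapia,atrazine-chlorpyrifos,5,80.31,TRUE
tilapia,atrazine-chlorpyrifos,7,31.00,TRUE
tilapia,atrazine-chlorpyrifos,9,15.19,TRUE
tilapia,atrazine-chlorpyrifos,11,8.57,TRUE
tilapia,atrazine-lambda-cyhalothrin,2.5,501.43,FALSE
tilapia,atrazine-lambda-cyhalothrin,5,70.72,FALSE
tilapia,atrazine-lambda-cyhalothrin,7.5,22.49,FALSE
tilapia,atrazine-lambda-cyhalothrin,10,9.97,FALSE
tilapia,atrazine-lambda-cyhalothrin,12.5,5.31,FALSE
tilapia,mancozeb-chlorpyrifos,1.5,1696.58,FALSE
tilapia,mancozeb-chlorpyrifos,2.25,186.99,FALSE
tilapia,mancozeb-chlorpyrifos,3,39.11,TRUE
tilapia,mancozeb-chlorpyrifos,3.75,11.62,FALSE
tilapia,mancozeb-chlorpyrifos,4.5,4.31,FALSE
tilapia,mancozeb-lambda-cyhalothrin,1.3,3059.71,TRUE
tilapia,mancozeb-lambda-cyhalothrin,2.1,232.65,TRUE
tilapia,mancozeb-lambda-cyhalothrin,2.9,40.49,TRUE
tilapia,mancozeb-lambda-cyhalothrin,3.7,10.79,TRUE
tilapia,mancozeb-lambda-cyhalothrin,4.5,3.72,TRUE
tilapia,lambda-cyhalothrin-chlorpyrifos,0.12,751.57,TRUE
tilapia,lambda-cyhalothrin-chlorpyrifos,0.15,172.88,TRUE
tilapia,lambda-cyhalothrin-chlorpyrifos,0.18,50.46,TRUE
tilapia,lambda-cyhalothrin-chlorpyrifos,0.21,17.63,TRUE
tilapia,lambda-cyhalothrin-chlorpyrifos,0.24,7.06,TRUE
tilapia,quaternary,3,672.17,TRUE
tilapia,quaternary,5.5,119.02,TRUE
tilapia,quaternary,8,39.76,TRUE
tilapia,quaternary,10.5,17.36,TRUE
tilapia,quaternary,13,8.73,TRUE
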