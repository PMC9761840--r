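species,chemical,a,b,r2,n
catfish,atrazine,14.033,-3.358,0.758,5
catfish,chlorpyrifos,2.211,-3.069,0.984,5
catfish,mancozeb,12.244,-2.397,0.892,5
catfish,lambda-cyhalothrin,-25.581,-3.784,0.915,5
tilapia,atrazine,8.906,-1.826,0.982,4
tilapia,chlorpyrifos,-8.373,-5.889,0.939,4
tilapia,mancozeb,9.482,-4.439,0.988,4
tilapia,lambda-cyhalothrin,-4.161,-1.725,0.884,6
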