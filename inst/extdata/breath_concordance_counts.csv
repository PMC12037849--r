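device,group,tp,fp,fn,tn,sensitivity_pct,specificity_pct,ppv_pct,npv_pct,f1
amue_link,training,2915,564,1242,183343,70.1,99.7,83.8,99.3,0.763
amue_link,test,1809,459,524,98715,77.5,99.5,79.8,99.5,0.786
xperia,training,3970,504,1769,205783,69.2,99.8,88.7,99.1,0.777
xperia,test,2359,398,634,109034,78.8,99.6,85.6,99.4,0.821
iphone,training,1764,565,924,146349,65.6,99.6,75.7,99.4,0.703
iphone,test,1281,223,433,75765,74.7,99.7,85.2,99.4,0.796
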