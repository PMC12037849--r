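device,group,rei_class,no_sa,mild,moderate,severe
amue_link,training,no_sa,2,1,0,0
amue_link,training,mild,3,7,3,0
amue_link,training,moderate,1,1,2,1
amue_link,training,severe,0,0,1,9
amue_link,test,no_sa,1,0,0,0
amue_link,test,mild,0,4,1,0
amue_link,test,moderate,1,1,1,0
amue_link,test,severe,0,0,1,5
xperia,training,no_sa,1,0,0,0
xperia,training,mild,2,6,1,0
xperia,training,moderate,0,1,5,1
xperia,training,severe,0,0,2,11
xperia,test,no_sa,0,0,0,0
xperia,test,mild,2,2,1,0
xperia,test,moderate,0,1,4,0
xperia,test,severe,0,0,1,6
iphone,training,no_sa,3,0,0,0
iphone,training,mild,2,4,1,0
iphone,training,moderate,1,2,3,2
iphone,training,severe,0,0,0,4
iphone,test,no_sa,0,1,0,0
iphone,test,mild,3,1,0,0
iphone,test,moderate,0,1,3,0
iphone,test,severe,0,0,0,3
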