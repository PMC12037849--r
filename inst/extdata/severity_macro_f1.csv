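device,group,macro_f1,verified
amue_link,training,0.586,TRUE
xperia,training,0.699,TRUE
iphone,training,0.646,TRUE
amue_link,test,0.677,TRUE
xperia,test,0.788,FALSE
iphone,test,0.714,FALSE
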