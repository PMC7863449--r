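name,tp,fn,fp,tn
CM1,100,1,5000,94900
CM2,90000,10000,1,9
CM3,90000,0,10,1
A@1,70,30,30,70
A@2,7,3,57,133
B@1,80,20,20,80
B@2,8,2,38,152
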