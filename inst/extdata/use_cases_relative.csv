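# relative=true
name,tp,fn,fp,tn
relCM1,0.000999,0.00000999,0.05,0.94899101
relA@1,0.35,0.15,0.15,0.35
relB@2,0.04,0.01,0.19,0.76
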