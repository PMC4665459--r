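#dtabayes schema: verification
category,s,r,u
1,31,48,117
2,298,26,150
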