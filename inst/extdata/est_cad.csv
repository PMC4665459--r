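#dtabayes schema: 2x2
test,disease,count
0,0,327
0,1,208
1,0,115
1,1,818
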