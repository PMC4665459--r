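#dtabayes schema: paired
disease,test1,test2,count
1,0,0,12
1,0,1,0
1,1,0,10
1,1,1,36
0,0,0,168
0,0,1,0
0,1,0,30
0,1,1,38
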