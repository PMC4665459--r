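#dtabayes schema: paired
disease,test1,test2,count
1,0,0,22
1,0,1,191
1,1,0,30
1,1,1,752
0,0,0,148
0,0,1,167
0,1,0,49
0,1,1,71
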