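#dtabayes schema: verification
category,s,r,u
1,72,308,92
2,54,127,66
3,121,78,76
4,145,33,10
5,245,77,5
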